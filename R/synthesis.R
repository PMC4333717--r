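#' Default planted-region plan
#'
#' Interleaves methylated (M), intermediate (IM) and unmethylated (U)
#' regions so every IM region is flanked by fully modified neighbourhood,
#' mimicking the mostly bimodal methylome in which IM islands sit.
#'
#' @param n_each Regions per state (default 50: 50 IM among 100 M/U).
#' @param cpgs_per_region CpGs per planted region (default 10).
#' @return data.frame with columns `state`, `n_cpgs`.
#' @export
default_region_plan <- function(n_each = 50L, cpgs_per_region = 10L) {
  data.frame(state = rep(c("M", "IM", "U"), times = n_each),
             n_cpgs = as.integer(cpgs_per_region),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic methylome generator
#'
#' Defines the study conditions emulated by the generator: clustered CpG
#' positions (geometric inter-CpG gaps), planted state regions, and
#' state-dependent Poisson read counts. Default Poisson means put planted
#' regions on the normalized per-CpG density scale: methylated CpGs at
#' MeDIP 8 / MRE 0.1, unmethylated at 0.1 / 8, intermediate at 4 / 4
#' (both assays moderate), background at 0.1 / 0.1.
#'
#' @param n_cpgs Total CpGs (default 6000).
#' @param mean_gap Mean inter-CpG gap in bp (geometric; default 80).
#' @param region_plan data.frame `state`, `n_cpgs`
#'   (default [default_region_plan()]).
#' @param rates Named list of per-state `c(medip=, mre=)` Poisson means.
#' @param background_rate `c(medip=, mre=)` means for inter-region CpGs.
#' @param allelic_plan Optional data.frame `scheme` ("ASM"/"AIM"),
#'   `n_snps`, `coverage`, and optionally `purity` (default 0.95) for
#'   [simulate_allelic()].
#' @param chrom Chromosome name for the simulated genome.
#' @param seed Integer seed (required; all draws are reproducible).
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_cpgs = 6000L, mean_gap = 80,
                              region_plan = default_region_plan(),
                              rates = list(M = c(medip = 8, mre = 0.1),
                                           U = c(medip = 0.1, mre = 8),
                                           IM = c(medip = 4, mre = 4)),
                              background_rate = c(medip = 0.1, mre = 0.1),
                              allelic_plan = NULL, chrom = "sim1", seed) {
  if (missing(seed)) stop("simulation_config: a seed is required")
  if (nrow(region_plan) &&
      !all(region_plan$state %in% c("M", "U", "IM")))
    stop("simulation_config: region states must be M, U or IM")
  if (any(unlist(rates) < 0) || any(background_rate < 0))
    stop("simulation_config: rates must be >= 0")
  if (sum(region_plan$n_cpgs) > n_cpgs)
    stop("simulation_config: region plan needs ", sum(region_plan$n_cpgs),
         " CpGs but n_cpgs is ", n_cpgs)
  structure(list(n_cpgs = as.integer(n_cpgs), mean_gap = mean_gap,
                 region_plan = region_plan, rates = rates,
                 background_rate = background_rate,
                 allelic_plan = allelic_plan, chrom = chrom,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a planted-state genome
#'
#' Draws CpG positions (gap = 1 + geometric with the configured mean) and
#' lays the planned regions left to right, separating them with
#' evenly-split background CpGs. Deterministic under the config seed.
#'
#' @param config [simulation_config()].
#' @return Object of class `truth_set`: `positions` (data.frame `chrom`,
#'   `pos`, `state`), `regions` (data.frame `chrom`, `start`, `end`,
#'   `state`, half-open over the member CpGs), `snps` (NULL until
#'   [simulate_allelic()]), and the config.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cpgs
  plan <- config$region_plan
  gaps <- withr::with_seed(config$seed,
                           stats::rgeom(n - 1L, 1 / config$mean_gap) + 1L)
  pos <- cumsum(c(1000L, gaps))
  n_regions <- nrow(plan)
  n_bg <- n - sum(plan$n_cpgs)
  slots <- n_regions + 1L
  bg_per_slot <- rep(n_bg %/% slots, slots)
  extra <- n_bg %% slots
  if (extra) bg_per_slot[seq_len(extra)] <- bg_per_slot[seq_len(extra)] + 1L
  state <- character(n)
  region_rows <- vector("list", n_regions)
  i <- 0L
  for (r in seq_len(slots)) {
    if (bg_per_slot[r] > 0) {
      state[i + seq_len(bg_per_slot[r])] <- "background"
      i <- i + bg_per_slot[r]
    }
    if (r <= n_regions) {
      k <- plan$n_cpgs[r]
      state[i + seq_len(k)] <- plan$state[r]
      region_rows[[r]] <- data.frame(chrom = config$chrom,
                                     start = pos[i + 1L],
                                     end = pos[i + k] + 1L,
                                     state = plan$state[r],
                                     stringsAsFactors = FALSE)
      i <- i + k
    }
  }
  regions <- do.call(rbind, region_rows)
  if (is.null(regions))
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), state = character())
  structure(list(positions = data.frame(chrom = config$chrom, pos = pos,
                                        state = state,
                                        stringsAsFactors = FALSE),
                 regions = regions, snps = NULL, config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d CpGs, %d planted regions (%s)\n",
              nrow(x$positions), nrow(x$regions),
              paste(sprintf("%s:%d", names(table(x$regions$state)),
                            table(x$regions$state)), collapse = ", ")))
  invisible(x)
}

#' Simulate paired MeDIP/MRE counts over a planted genome
#'
#' Per-CpG counts are independent Poisson draws with the means of the
#' CpG's planted state (or the background rate). Seeded with
#' `config$seed + 1` so the count draw is independent of the genome draw.
#'
#' @param truth [simulate_genome()] output.
#' @param config [simulation_config()].
#' @return A [cpg_track()].
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"))
  st <- truth$positions$state
  lam <- rbind(background = config$background_rate,
               do.call(rbind, config$rates))
  lam_medip <- lam[st, "medip"]
  lam_mre <- lam[st, "mre"]
  n <- nrow(truth$positions)
  counts <- withr::with_seed(config$seed + 1L,
                             list(medip = stats::rpois(n, lam_medip),
                                  mre = stats::rpois(n, lam_mre)))
  cpg_track(data.frame(chrom = truth$positions$chrom,
                       pos = truth$positions$pos,
                       medip = counts$medip, mre = counts$mre,
                       stringsAsFactors = FALSE),
            sample_id = sprintf("sim_seed%d", config$seed))
}

#' Simulate allelic read counts at SNPs inside planted IM regions
#'
#' Implements the two allelic schemes behind intermediate methylation.
#' ASM (allele-specific): the MeDIP assay draws reads from one allele and
#' the MRE assay from the other, each with purity `purity`
#' (`medip_ref ~ Binomial(coverage, purity)`,
#' `mre_alt ~ Binomial(coverage, purity)`). AIM (allele-independent): both
#' assays sample both alleles evenly (`Binomial(coverage, 0.5)`). Seeded
#' with `config$seed + 2`.
#'
#' @param truth [simulate_genome()] output (needs planted IM regions when
#'   an allelic plan is present).
#' @param config [simulation_config()] with a non-NULL `allelic_plan`.
#' @return data.frame of allelic counts (readable by [classify_snps()])
#'   with an extra `true_class` column.
#' @export
simulate_allelic <- function(truth, config = truth$config) {
  plan <- config$allelic_plan
  if (is.null(plan)) stop("simulate_allelic: config has no allelic plan")
  if (!"purity" %in% names(plan)) plan$purity <- 0.95
  im <- truth$regions[truth$regions$state == "IM", , drop = FALSE]
  if (!nrow(im)) stop("simulate_allelic: no planted IM regions")
  bases <- c("A", "C", "G", "T")
  withr::with_seed(config$seed + 2L, {
    out <- lapply(seq_len(nrow(plan)), function(r) {
      k <- plan$n_snps[r]; cov <- plan$coverage[r]
      scheme <- plan$scheme[r]; purity <- plan$purity[r]
      reg <- im[1L + (seq_len(k) - 1L) %% nrow(im), , drop = FALSE]
      pos <- reg$start + vapply(reg$end - reg$start, function(w)
        sample.int(w, 1L) - 1L, integer(1))
      ref <- sample(bases, k, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                    character(1))
      if (scheme == "ASM") {
        medip_ref <- stats::rbinom(k, cov, purity)
        mre_alt <- stats::rbinom(k, cov, purity)
        data.frame(snp_id = sprintf("%s_snp%d", scheme, seq_len(k)),
                   chrom = reg$chrom, pos = pos, ref = ref, alt = alt,
                   medip_ref = medip_ref, medip_alt = cov - medip_ref,
                   mre_ref = cov - mre_alt, mre_alt = mre_alt,
                   true_class = "ASM", stringsAsFactors = FALSE)
      } else if (scheme == "AIM") {
        medip_ref <- stats::rbinom(k, cov, 0.5)
        mre_ref <- stats::rbinom(k, cov, 0.5)
        data.frame(snp_id = sprintf("%s_snp%d", scheme, seq_len(k)),
                   chrom = reg$chrom, pos = pos, ref = ref, alt = alt,
                   medip_ref = medip_ref, medip_alt = cov - medip_ref,
                   mre_ref = mre_ref, mre_alt = cov - mre_ref,
                   true_class = "AIM", stringsAsFactors = FALSE)
      } else stop("simulate_allelic: unknown scheme '", scheme, "'")
    })
    snps <- do.call(rbind, out)
    snps$snp_id <- make.unique(snps$snp_id)
    rownames(snps) <- NULL
    snps
  })
}

#' Score IM call recovery against planted truth
#'
#' A call matches a true IM region when their reciprocal overlap is at
#' least 50% (or, when `slack_bp` is given, when both edges are within
#' `slack_bp`). Precision is the fraction of calls matching some truth
#' region; recall the fraction of truth regions matched by some call;
#' boundary error pools the absolute start and end differences over
#' matched pairs.
#'
#' @param calls Call data.frame (`chrom`, `start`, `end`).
#' @param truth [simulate_genome()] output or a region data.frame with a
#'   `state` column (IM rows are used).
#' @param slack_bp Optional edge slack in bp for the alternative matching
#'   route.
#' @return list: `precision` (NA with a message when there are no calls),
#'   `recall`, `median_boundary_error`, `n_calls`, `n_truth`,
#'   `n_matched_calls`, `n_matched_truth`.
#' @export
evaluate_recovery <- function(calls, truth, slack_bp = NULL) {
  tr <- if (inherits(truth, "truth_set")) truth$regions else truth
  tr <- tr[tr$state == "IM", , drop = FALSE]
  n_calls <- nrow(calls); n_truth <- nrow(tr)
  if (!n_calls) {
    message("evaluate_recovery: no calls; precision undefined")
    return(list(precision = NA_real_, recall = 0,
                median_boundary_error = NA_real_, n_calls = 0L,
                n_truth = n_truth, n_matched_calls = 0L,
                n_matched_truth = 0L))
  }
  cg <- regions_to_granges(calls); tg <- regions_to_granges(tr)
  hits <- GenomicRanges::findOverlaps(cg, tg)
  q <- S4Vectors::queryHits(hits); su <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(cg[q], tg[su]))
  match_ok <- ov / GenomicRanges::width(cg[q]) >= 0.5 &
    ov / GenomicRanges::width(tg[su]) >= 0.5
  if (!is.null(slack_bp)) {
    edge_ok <- abs(calls$start[q] - tr$start[su]) <= slack_bp &
      abs(calls$end[q] - tr$end[su]) <= slack_bp
    match_ok <- match_ok | edge_ok
  }
  q <- q[match_ok]; su <- su[match_ok]
  errs <- c(abs(calls$start[q] - tr$start[su]),
            abs(calls$end[q] - tr$end[su]))
  list(precision = length(unique(q)) / n_calls,
       recall = length(unique(su)) / max(n_truth, 1L),
       median_boundary_error = if (length(errs)) stats::median(errs)
       else NA_real_,
       n_calls = n_calls, n_truth = n_truth,
       n_matched_calls = length(unique(q)),
       n_matched_truth = length(unique(su)))
}

#' Synthetic gene/exon expression fixture tied to region states
#'
#' Builds a fixture in which each gene carries one nearby region of a
#' known methylation state and expression depends on that state:
#' transcript RPKM is log-normal with unmethylated-associated genes
#' highest, IM-associated intermediate and methylated-associated lowest
#' (meanlog log(20), log(8), log(2), sdlog 1); relative exon expression is
#' Beta-distributed with the reversed ordering (means 0.85, 0.65, 0.45
#' for M, IM, U; precision 20). Regions sit 2 kb downstream of their TSS
#' (within the 10 kb gene window) and 0.8 kb from their exon (within the
#' 1 kb exon window), so the association operations are exercised.
#'
#' @param n_per_group Genes per state group (default 300).
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return list: `regions` (with `state`), `tss_table`, `exon_table`,
#'   `expression` (data.frame `transcript_id`, `rpkm`), `exon_expression`
#'   (data.frame `exon_id`, `transcript_id`, `R_e`, `R_t`).
#' @export
simulate_expression_fixture <- function(n_per_group = 300L, seed = 1L,
                                        chrom = "sim1") {
  states <- rep(c("unmethylated", "IM", "methylated"), each = n_per_group)
  n <- length(states)
  meanlog <- c(unmethylated = log(20), IM = log(8), methylated = log(2))
  incl_mean <- c(methylated = 0.85, IM = 0.65, unmethylated = 0.45)
  tss <- 20000L * seq_len(n)
  withr::with_seed(seed, {
    rpkm_t <- stats::rlnorm(n, meanlog[states], 1)
    kappa <- 20
    incl <- stats::rbeta(n, incl_mean[states] * kappa,
                         (1 - incl_mean[states]) * kappa)
  })
  ids <- sprintf("tx%04d", seq_len(n))
  list(regions = data.frame(chrom = chrom, start = tss + 2000L,
                            end = tss + 2400L, state = states,
                            region_id = seq_len(n),
                            stringsAsFactors = FALSE),
       tss_table = data.frame(transcript_id = ids, chrom = chrom,
                              tss = tss, strand = "+",
                              stringsAsFactors = FALSE),
       exon_table = data.frame(exon_id = sprintf("%s_e1", ids),
                               transcript_id = ids, chrom = chrom,
                               start = tss + 1000L, end = tss + 1200L,
                               stringsAsFactors = FALSE),
       expression = data.frame(transcript_id = ids, rpkm = rpkm_t,
                               stringsAsFactors = FALSE),
       exon_expression = data.frame(exon_id = sprintf("%s_e1", ids),
                                    transcript_id = ids,
                                    R_e = incl * rpkm_t, R_t = rpkm_t,
                                    stringsAsFactors = FALSE))
}
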