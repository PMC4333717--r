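#' Parameters for heterozygosity calling and ASM/AIM classification
#'
#' Defaults follow the published criteria: at least 9 reads in both the
#' MeDIP and MRE assays, at most 100 MRE reads (PCR-bias guard), each
#' allele carrying at least 30% of reads in at least one assay to call a
#' SNP heterozygous; at least 75% same-allele MeDIP reads with at least 75%
#' opposite-allele MRE reads plus Fisher P < 0.01 for allele-specific
#' methylation (ASM); no assay above 70% same-allele reads plus Fisher
#' P > 0.01 for allele-independent methylation (AIM); and at least 2
#' consistent SNPs to label a region.
#'
#' @param min_cov Minimum reads per assay.
#' @param mre_max_cov Maximum MRE reads.
#' @param het_min_frac Minimum per-allele fraction for heterozygosity.
#' @param asm_min_frac Minimum major/opposite-allele fraction for ASM.
#' @param aim_max_frac Maximum major-allele fraction for AIM.
#' @param alpha Fisher's exact test significance level.
#' @param region_min_snps Minimum consistent SNPs for a region verdict.
#' @return Object of class `allelic_params`.
#' @export
allelic_params <- function(min_cov = 9L, mre_max_cov = 100L,
                           het_min_frac = 0.30, asm_min_frac = 0.75,
                           aim_max_frac = 0.70, alpha = 0.01,
                           region_min_snps = 2L) {
  if (!(het_min_frac > 0 && het_min_frac < 0.5 && aim_max_frac > 0.5 &&
        asm_min_frac > aim_max_frac && asm_min_frac < 1))
    stop("allelic_params: need 0 < het_min_frac < 0.5 < aim_max_frac < ",
         "asm_min_frac < 1")
  structure(list(min_cov = as.integer(min_cov),
                 mre_max_cov = as.integer(mre_max_cov),
                 het_min_frac = het_min_frac, asm_min_frac = asm_min_frac,
                 aim_max_frac = aim_max_frac, alpha = alpha,
                 region_min_snps = as.integer(region_min_snps)),
            class = "allelic_params")
}

check_allelic_counts <- function(x) {
  need <- c("snp_id", "chrom", "pos", "ref", "alt",
            "medip_ref", "medip_alt", "mre_ref", "mre_alt")
  if (!all(need %in% names(x)))
    stop("allelic counts need columns ", paste(need, collapse = ", "))
  cnt <- c("medip_ref", "medip_alt", "mre_ref", "mre_alt")
  if (nrow(x)) {
    if (any(unlist(x[cnt]) < 0)) stop("allelic counts must be >= 0")
    if (any(x$ref == x$alt)) stop("ref and alt alleles must differ")
  }
  x
}

#' Read a per-SNP allelic count table
#'
#' Tab-separated with header: `snp_id chrom pos ref alt medip_ref
#' medip_alt mre_ref mre_alt` (pos 0-based; counts are reads carrying each
#' allele in each assay).
#'
#' @param path TSV path (optionally .gz).
#' @return data.frame of allelic counts.
#' @export
read_allelic_counts <- function(path) {
  if (!file.exists(path)) stop("read_allelic_counts: no such file: ", path)
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  check_allelic_counts(x)
}

#' Call SNP heterozygosity from assay read counts
#'
#' A SNP is heterozygous when both assays reach the minimum coverage, the
#' MRE assay does not exceed its maximum coverage, and each allele is
#' represented by at least `het_min_frac` of the reads of at least one
#' assay (either assay may vouch for either allele: at an
#' allele-specifically methylated SNP the two alleles are carried by
#' different assays, so requiring both alleles in the same assay would
#' exclude exactly the SNPs of interest).
#'
#' @param counts data.frame of allelic counts (one or more rows).
#' @param params [allelic_params()].
#' @return Logical vector, one element per SNP.
#' @export
call_heterozygous <- function(counts, params = allelic_params()) {
  counts <- check_allelic_counts(counts)
  medip_tot <- counts$medip_ref + counts$medip_alt
  mre_tot <- counts$mre_ref + counts$mre_alt
  frac <- function(x, tot) ifelse(tot > 0, x / tot, 0)
  ref_ok <- frac(counts$medip_ref, medip_tot) >= params$het_min_frac |
    frac(counts$mre_ref, mre_tot) >= params$het_min_frac
  alt_ok <- frac(counts$medip_alt, medip_tot) >= params$het_min_frac |
    frac(counts$mre_alt, mre_tot) >= params$het_min_frac
  medip_tot >= params$min_cov & mre_tot >= params$min_cov &
    mre_tot <= params$mre_max_cov & ref_ok & alt_ok
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over the hypergeometric
#' support with margins fixed, the probabilities of all tables at most as
#' probable as the observed one (with a small relative tolerance for
#' floating-point ties, as in [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = assays,
#'   columns = alleles: `[[a, b], [c, d]]`.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(9, 0, 0, 9)   # 2 / choose(18, 9)
#' fisher_exact_2x2(5, 5, 5, 5)   # 1
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("fisher_exact_2x2: cells must be non-negative integers")
  if (sum(cells) == 0) stop("fisher_exact_2x2: all-zero table")
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Classify heterozygous SNPs as ASM, AIM or unclassified
#'
#' For each SNP the 2x2 assay-by-allele table (MeDIP ref/alt vs MRE
#' ref/alt) is tested with Fisher's exact test; its p-value measures how
#' strongly the two assays segregate the alleles, which is the
#' allele-specific methylation phenomenon. A SNP is ASM when the MeDIP
#' major-allele fraction is at least `asm_min_frac`, the MRE fraction of
#' the opposite allele is at least `asm_min_frac`, and Fisher P < alpha.
#' It is AIM when neither assay's major fraction exceeds `aim_max_frac`
#' and Fisher P > alpha. Exact 50/50 ties count as major fraction 0.5.
#' SNPs failing heterozygosity are `not_het`; remaining heterozygous SNPs
#' are `het_unclassified`. The criteria make ASM and AIM mutually
#' exclusive, and the classification is invariant to swapping the ref/alt
#' labels.
#'
#' @param counts data.frame of allelic counts.
#' @param params [allelic_params()].
#' @return The input with columns `status` (`not_het`, `het_unclassified`,
#'   `ASM`, `AIM`), `fisher_p`, `medip_major_frac`, `mre_major_frac`.
#' @export
classify_snps <- function(counts, params = allelic_params()) {
  counts <- check_allelic_counts(counts)
  n <- nrow(counts)
  het <- call_heterozygous(counts, params)
  medip_tot <- counts$medip_ref + counts$medip_alt
  mre_tot <- counts$mre_ref + counts$mre_alt
  medip_major <- ifelse(medip_tot > 0,
                        pmax(counts$medip_ref, counts$medip_alt) / medip_tot,
                        NA_real_)
  mre_major <- ifelse(mre_tot > 0,
                      pmax(counts$mre_ref, counts$mre_alt) / mre_tot,
                      NA_real_)
  fisher_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tot <- medip_tot[i] + mre_tot[i]
    if (tot > 0)
      fisher_p[i] <- fisher_exact_2x2(counts$medip_ref[i],
                                      counts$medip_alt[i],
                                      counts$mre_ref[i], counts$mre_alt[i])
  }
  # ASM: MeDIP majority on one allele, MRE majority on the other
  medip_major_is_ref <- counts$medip_ref >= counts$medip_alt
  mre_opposite_frac <- ifelse(mre_tot > 0,
                              ifelse(medip_major_is_ref, counts$mre_alt,
                                     counts$mre_ref) / mre_tot,
                              NA_real_)
  asm <- het & medip_major >= params$asm_min_frac &
    mre_opposite_frac >= params$asm_min_frac & fisher_p < params$alpha
  aim <- het & medip_major <= params$aim_max_frac &
    mre_major <= params$aim_max_frac & fisher_p > params$alpha
  status <- rep("het_unclassified", n)
  status[!het] <- "not_het"
  status[asm %in% TRUE] <- "ASM"
  status[aim %in% TRUE] <- "AIM"
  counts$status <- status
  counts$fisher_p <- fisher_p
  counts$medip_major_frac <- medip_major
  counts$mre_major_frac <- mre_major
  counts
}

#' Region-level ASM/AIM verdict from its SNP classifications
#'
#' A region is ASM when it contains at least `region_min_snps` ASM SNPs
#' and no AIM SNPs; AIM symmetrically. Regions containing both ASM and
#' AIM SNPs are ignored (`ambiguous_ignored`); regions with fewer than
#' `region_min_snps` consistent SNPs are `unclassified`.
#'
#' @param region Single-row data.frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param snps Classified SNPs from [classify_snps()]; all must fall
#'   within the region.
#' @param params [allelic_params()].
#' @return list with `region`, `n_asm`, `n_aim`, `verdict`.
#' @export
classify_region <- function(region, snps, params = allelic_params()) {
  region <- as.list(region)
  if (nrow(snps)) {
    outside <- snps$chrom != region$chrom | snps$pos < region$start |
      snps$pos >= region$end
    if (any(outside))
      stop("classify_region: SNP ", snps$snp_id[outside][1],
           " lies outside the region")
  }
  n_asm <- sum(snps$status == "ASM")
  n_aim <- sum(snps$status == "AIM")
  verdict <- if (n_asm >= 1 && n_aim >= 1) "ambiguous_ignored"
  else if (n_asm >= params$region_min_snps) "ASM"
  else if (n_aim >= params$region_min_snps) "AIM"
  else "unclassified"
  list(region = region, n_asm = n_asm, n_aim = n_aim, verdict = verdict)
}

#' Correlation of allelic preference between two signals
#'
#' Pearson correlation, across shared SNPs, of the reference-allele read
#' fraction of two signals (e.g. a histone mark vs MeDIP-Seq). Positive
#' values mean the two signals sit on the same allele.
#'
#' @param snp_skews_a,snp_skews_b Named numeric vectors (names = SNP ids,
#'   values = reference-allele fractions).
#' @return Pearson correlation coefficient; `NA` with a warning when
#'   either signal has zero variance across the shared SNPs.
#' @export
allelic_preference_correlation <- function(snp_skews_a, snp_skews_b) {
  shared <- intersect(names(snp_skews_a), names(snp_skews_b))
  if (length(shared) < 3)
    stop("allelic_preference_correlation: fewer than 3 shared SNPs")
  a <- snp_skews_a[shared]; b <- snp_skews_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("allelic_preference_correlation: zero variance in at least ",
            "one signal; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "pearson")
}

#' Write classified SNPs to TSV
#'
#' @param snps Output of [classify_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_classifications <- function(snps, path) {
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
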