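#' Call methylated / unmethylated states over candidate regions
#'
#' Applies the read-count state definitions: within a region, a CpG is an
#' "unmethylated CpG" when it carries at least `min_reads` MRE-Seq reads
#' and no MeDIP-Seq reads, and a "methylated CpG" symmetrically. The
#' region is unmethylated (methylated) when at least `frac_cpgs` of its
#' CpGs qualify; otherwise its state is "neither". The two per-CpG
#' predicates are disjoint, so no region can satisfy both rules.
#'
#' @param track [cpg_track()] with raw read counts.
#' @param regions Region data.frame (`chrom`, `start`, `end`).
#' @param min_reads Minimum reads in the dominant assay (default 4).
#' @param frac_cpgs Minimum fraction of qualifying CpGs (default 0.75).
#' @return `regions` with columns `state` and `n_cpgs` added. Regions
#'   containing no CpGs get state "neither" with a warning.
#' @export
call_state_regions <- function(track, regions, min_reads = 4L,
                               frac_cpgs = 0.75) {
  stopifnot(inherits(track, "cpg_track"))
  regions <- as_region_df(regions)
  s <- track$sites
  cpg_gr <- GenomicRanges::GRanges(s$chrom,
                                   IRanges::IRanges(s$pos + 1L, s$pos + 1L))
  hits <- GenomicRanges::findOverlaps(cpg_gr, regions_to_granges(regions))
  is_u <- s$mre >= min_reads & s$medip == 0
  is_m <- s$medip >= min_reads & s$mre == 0
  n <- nrow(regions)
  n_cpgs <- integer(n); fu <- numeric(n); fm <- numeric(n)
  idx <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  for (nm in names(idx)) {
    i <- as.integer(nm)
    n_cpgs[i] <- length(idx[[nm]])
    fu[i] <- mean(is_u[idx[[nm]]])
    fm[i] <- mean(is_m[idx[[nm]]])
  }
  if (any(n_cpgs == 0))
    warning("call_state_regions: ", sum(n_cpgs == 0),
            " region(s) contain no CpGs; state set to 'neither'")
  regions$state <- ifelse(n_cpgs == 0, "neither",
                          ifelse(fu >= frac_cpgs, "unmethylated",
                                 ifelse(fm >= frac_cpgs, "methylated",
                                        "neither")))
  regions$n_cpgs <- n_cpgs
  regions
}

#' Reads per kilobase per million mapped reads
#'
#' @param read_count Reads in the feature (vectorized).
#' @param feature_length_bp Feature length in bp (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return `read_count * 1e9 / (feature_length_bp * total_mapped_reads)`.
#' @export
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
rpkm <- function(read_count, feature_length_bp, total_mapped_reads) {
  if (any(feature_length_bp <= 0)) stop("rpkm: feature length must be > 0")
  if (any(total_mapped_reads <= 0)) stop("rpkm: total reads must be > 0")
  read_count * 1e9 / (feature_length_bp * total_mapped_reads)
}

#' Binned signal profile around region centres
#'
#' Tiles `[centre - flank, centre + flank)` around each region's midpoint
#' into `2 * flank / bin_width` bins, assigns each signal read to the bin
#' containing its midpoint, and expresses bin values as RPKM. Intended for
#' histone ChIP-Seq or DNase read intervals around IM / methylated /
#' unmethylated regions. Per-bin mean and standard error across regions
#' summarise the profile (binned means stand in for the generalized
#' additive model smoothing used for presentation in the original
#' figures).
#'
#' @param regions Region data.frame.
#' @param signal_reads data.frame of read intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param total_reads Library size for RPKM scaling.
#' @param bin_width Bin width in bp (default 100).
#' @param flank Half-window in bp (default 5000).
#' @param label Optional label for the region set.
#' @return Object of class `signal_profile`: `matrix` (regions x bins,
#'   RPKM), `bin_mean`, `bin_sem`, `bin_offsets` (bin start offsets from
#'   the region centre), plus the parameters.
#' @export
bin_signal_profile <- function(regions, signal_reads, total_reads,
                               bin_width = 100L, flank = 5000L,
                               label = NA_character_) {
  regions <- as_region_df(regions)
  if (!nrow(regions)) stop("bin_signal_profile: no regions")
  if ((2 * flank) %% bin_width != 0)
    stop("bin_signal_profile: 2*flank must be a multiple of bin_width")
  n_bins <- as.integer(2 * flank / bin_width)
  centers <- (regions$start + regions$end) %/% 2L
  win_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(centers - flank + 1L,
                                                    centers + flank))
  mids <- (signal_reads$start + signal_reads$end) %/% 2L
  mid_gr <- GenomicRanges::GRanges(as.character(signal_reads$chrom),
                                   IRanges::IRanges(mids + 1L, mids + 1L))
  hits <- GenomicRanges::findOverlaps(mid_gr, win_gr)
  q <- S4Vectors::queryHits(hits); su <- S4Vectors::subjectHits(hits)
  bin <- ((mids[q] - (centers[su] - flank)) %/% bin_width) + 1L
  counts <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  if (length(q)) {
    tab <- table(factor(su, levels = seq_len(nrow(regions))),
                 factor(bin, levels = seq_len(n_bins)))
    counts <- matrix(as.numeric(tab), nrow = nrow(regions))
  }
  mat <- rpkm(counts, bin_width, total_reads)
  sem <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
  structure(list(region_set_label = label, matrix = mat,
                 bin_mean = colMeans(mat), bin_sem = sem,
                 bin_offsets = seq(-flank, flank - bin_width, by = bin_width),
                 bin_width = as.integer(bin_width),
                 flank = as.integer(flank), total_reads = total_reads),
            class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, ...) {
  cat(sprintf("signal_profile%s: %d regions x %d bins (%d bp bins, +/-%d bp)\n",
              if (is.na(x$region_set_label)) "" else
                paste0(" '", x$region_set_label, "'"),
              nrow(x$matrix), ncol(x$matrix), x$bin_width, x$flank))
  cat(sprintf("  mean RPKM range across bins: %.3g .. %.3g\n",
              min(x$bin_mean), max(x$bin_mean)))
  invisible(x)
}

# Distance from a point to a half-open region: 0 inside, else distance to
# the nearest covered base.
point_region_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos < end, 0L,
         ifelse(pos < start, start - pos, pos - (end - 1L)))
}

# Distance between two half-open intervals: 0 when they overlap, else the
# distance between their nearest covered bases (adjacent intervals are
# 1 bp apart).
interval_distance <- function(s1, e1, s2, e2) {
  ifelse(s1 < e2 & s2 < e1, 0L,
         ifelse(e1 <= s2, s2 - (e1 - 1L), s1 - (e2 - 1L)))
}

#' Associate regions with genes by TSS proximity
#'
#' Emits a (region, transcript) pair whenever the region lies within
#' `window` bp of the transcript's transcription start site (distance 0
#' when the region overlaps the TSS; otherwise distance from the nearest
#' region edge).
#'
#' @param regions Region data.frame; a `region_id` column is added from
#'   the row number when absent.
#' @param tss_table data.frame with `transcript_id`, `chrom`, `tss`
#'   (0-based position) and optionally `strand`.
#' @param window Maximum distance in bp (default 10,000).
#' @return data.frame of pairs: `region_id`, `transcript_id`, `distance`
#'   plus the region coordinates.
#' @export
associate_regions_to_genes <- function(regions, tss_table, window = 10000L) {
  regions <- as_region_df(regions)
  if (!"region_id" %in% names(regions))
    regions$region_id <- seq_len(nrow(regions))
  pairs <- merge(regions[c("region_id", "chrom", "start", "end")],
                 tss_table[c("transcript_id", "chrom", "tss")], by = "chrom")
  if (!nrow(pairs))
    return(data.frame(region_id = integer(), transcript_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), distance = integer()))
  pairs$distance <- point_region_distance(pairs$tss, pairs$start, pairs$end)
  out <- pairs[pairs$distance <= window,
               c("region_id", "transcript_id", "chrom", "start", "end",
                 "distance")]
  rownames(out) <- NULL
  out
}

#' Associate regions with exons by proximity
#'
#' Emits a (region, exon) pair whenever the region overlaps the exon or
#' lies within `window` bp of it.
#'
#' @param regions Region data.frame (`region_id` added when absent).
#' @param exon_table data.frame with `exon_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param window Maximum distance in bp (default 1,000).
#' @return data.frame of pairs with `distance`.
#' @export
associate_regions_to_exons <- function(regions, exon_table, window = 1000L) {
  regions <- as_region_df(regions)
  if (!"region_id" %in% names(regions))
    regions$region_id <- seq_len(nrow(regions))
  ex <- exon_table
  names(ex)[names(ex) == "start"] <- "exon_start"
  names(ex)[names(ex) == "end"] <- "exon_end"
  pairs <- merge(regions[c("region_id", "chrom", "start", "end")],
                 ex[c("exon_id", "transcript_id", "chrom", "exon_start",
                      "exon_end")], by = "chrom")
  if (!nrow(pairs))
    return(data.frame(region_id = integer(), exon_id = character(),
                      transcript_id = character(), distance = integer()))
  pairs$distance <- interval_distance(pairs$start, pairs$end,
                                      pairs$exon_start, pairs$exon_end)
  out <- pairs[pairs$distance <= window,
               c("region_id", "exon_id", "transcript_id", "chrom",
                 "start", "end", "exon_start", "exon_end", "distance")]
  rownames(out) <- NULL
  out
}

#' Relative exon expression
#'
#' Ratio of an exon's RPKM to its parent transcript's RPKM, a proxy for
#' exon inclusion. Exons on transcripts with non-positive RPKM are
#' excluded (`NA`) with a warning.
#'
#' @param R_e Exon RPKM (vectorized).
#' @param R_t Parent transcript RPKM.
#' @return `R_e / R_t`, `NA` where `R_t <= 0`.
#' @export
relative_exon_expression <- function(R_e, R_t) {
  out <- ifelse(R_t > 0, R_e / R_t, NA_real_)
  if (any(R_t <= 0))
    warning("relative_exon_expression: ", sum(R_t <= 0),
            " exon(s) on transcripts with zero expression excluded")
  out
}

#' Two-sided Wilcoxon rank-sum test between two groups
#'
#' Exact when the combined sample size is at most 20 and there are no
#' ties; otherwise the normal approximation with the tie-corrected
#' variance (no continuity correction, so identical groups give p = 1).
#'
#' @param values_a,values_b Numeric vectors (each non-empty).
#' @return Two-sided p-value.
#' @export
group_rank_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("group_rank_test: empty group")
  exact <- (length(values_a) + length(values_b)) <= 20 &&
    !anyDuplicated(c(values_a, values_b))
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact,
                       correct = FALSE)$p.value)
}

#' Pairwise sample distance matrix
#'
#' Jaccard distance (`1 - |intersection| / |union|` of the nonzero feature
#' sets; requires a binary matrix) or Canberra distance
#' (`sum(|x - y| / (|x| + |y|))` over features where the denominator is
#' nonzero; no rescaling by the number of contributing features).
#'
#' @param profile_matrix Numeric matrix, samples in rows, features in
#'   columns.
#' @param metric `"jaccard"` or `"canberra"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
sample_distance_matrix <- function(profile_matrix,
                                   metric = c("jaccard", "canberra")) {
  metric <- match.arg(metric)
  m <- as.matrix(profile_matrix)
  ns <- nrow(m)
  d <- matrix(0, ns, ns, dimnames = list(rownames(m), rownames(m)))
  if (metric == "jaccard") {
    if (!all(m %in% c(0, 1)))
      stop("sample_distance_matrix: jaccard requires a binary matrix")
    inter <- tcrossprod(m)
    sizes <- rowSums(m)
    uni <- outer(sizes, sizes, "+") - inter
    d <- 1 - ifelse(uni > 0, inter / uni, 1)
  } else {
    for (i in seq_len(ns)) {
      for (j in seq_len(ns)) {
        if (j <= i) next
        num <- abs(m[i, ] - m[j, ])
        den <- abs(m[i, ]) + abs(m[j, ])
        d[i, j] <- d[j, i] <- sum(num[den > 0] / den[den > 0])
      }
    }
  }
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering of a distance matrix
#'
#' @param dist_matrix Symmetric distance matrix, e.g. from
#'   [sample_distance_matrix()].
#' @return An [stats::hclust] tree (method "average").
#' @export
average_linkage_tree <- function(dist_matrix) {
  stats::hclust(stats::as.dist(dist_matrix), method = "average")
}

#' CpG-level overlap enrichment between two region sets with a permutation null
#'
#' The statistic is the number of universe CpGs covered by both region
#' sets. The null relocates each region of `set_a` (length preserved) to a
#' uniformly drawn universe CpG and recomputes the statistic; fold
#' enrichment is observed / mean(null) and the empirical p-value is the
#' permutation rank. A chi-squared statistic on the 2x2 CpG coverage table
#' (in/out of `set_a` x in/out of `set_b`) is also reported.
#'
#' @param set_a,set_b Region data.frames (non-empty).
#' @param cpg_universe data.frame with `chrom`, `pos` of all CpGs
#'   considered.
#' @param n_permutations Number of relocations (>= 1).
#' @param seed Integer seed.
#' @return list: `observed`, `expected`, `fold_enrichment`, `empirical_p`,
#'   `null`, `chisq_stat`, `chisq_p`, `n_permutations`, `seed`.
#' @export
overlap_enrichment <- function(set_a, set_b, cpg_universe,
                               n_permutations = 1000L, seed = 1L) {
  set_a <- as_region_df(set_a); set_b <- as_region_df(set_b)
  if (!nrow(set_a) || !nrow(set_b))
    stop("overlap_enrichment: empty region set")
  if (!nrow(cpg_universe)) stop("overlap_enrichment: empty CpG universe")
  if (n_permutations < 1L)
    stop("overlap_enrichment: n_permutations must be >= 1")
  uni_gr <- GenomicRanges::GRanges(as.character(cpg_universe$chrom),
                                   IRanges::IRanges(cpg_universe$pos + 1L,
                                                    cpg_universe$pos + 1L))
  covered <- function(regions_df) {
    hits <- GenomicRanges::findOverlaps(uni_gr,
                                        regions_to_granges(regions_df))
    seq_len(length(uni_gr)) %in% S4Vectors::queryHits(hits)
  }
  in_b <- covered(set_b)
  in_a <- covered(set_a)
  observed <- sum(in_a & in_b)
  widths <- set_a$end - set_a$start
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      anchor <- sample.int(nrow(cpg_universe), nrow(set_a), replace = TRUE)
      reloc <- data.frame(chrom = as.character(cpg_universe$chrom[anchor]),
                          start = cpg_universe$pos[anchor],
                          end = cpg_universe$pos[anchor] + widths)
      sum(covered(reloc) & in_b)
    }, numeric(1))
  })
  expected <- mean(null)
  chisq <- suppressWarnings(
    stats::chisq.test(table(factor(in_a, c(FALSE, TRUE)),
                            factor(in_b, c(FALSE, TRUE)))))
  list(observed = observed, expected = expected,
       fold_enrichment = if (expected > 0) observed / expected else Inf,
       empirical_p = (1 + sum(null >= observed)) / (n_permutations + 1),
       null = null, chisq_stat = unname(chisq$statistic),
       chisq_p = chisq$p.value,
       n_permutations = as.integer(n_permutations), seed = seed)
}
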