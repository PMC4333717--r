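#' Detection parameters for the IM segmentation pipeline
#'
#' Bundles every constant used by the maximum scoring segment caller and the
#' reference-set assembly. Defaults follow the published analysis: MeDIP-Seq
#' totals normalized to 50 million reads, MRE-Seq totals to 35 million,
#' minimum segment score 8.0, minimum region length 100 bp (applied at the
#' reference-set stage), regions merged across samples when within 100 bp,
#' and reference regions required in at least 2 samples. The overlap weight
#' `w` and the gap penalty rate `lambda` parameterise the score itself
#' (see [score_deltas()]); they have no published values and default to
#' `w = 1` (scores stay on the normalized read-count scale, so the 8.0
#' cutoff is meaningful) and `lambda = 0.01`/bp (100 bp of inter-CpG gap
#' costs one score unit).
#'
#' @param medip_target Total-count normalization target for MeDIP-Seq.
#' @param mre_target Total-count normalization target for MRE-Seq.
#' @param overlap_weight Positive scale `w` on the per-CpG reward/penalty.
#' @param gap_penalty_rate Penalty per bp of gap between consecutive CpGs.
#' @param min_score Minimum segment score retained by [apply_filters()].
#' @param min_length Minimum region length (bp), enforced for reference sets.
#' @param min_ref_samples Minimum supporting samples in the reference set.
#' @param merge_gap Maximum gap (bp) merged across samples.
#' @return An object of class `detection_params`.
#' @export
#' @examples
#' detection_params()
#' detection_params(overlap_weight = 2, gap_penalty_rate = 0.02)
detection_params <- function(medip_target = 50e6, mre_target = 35e6,
                             overlap_weight = 1.0, gap_penalty_rate = 0.01,
                             min_score = 8.0, min_length = 100L,
                             min_ref_samples = 2L, merge_gap = 100L) {
  p <- list(medip_target = medip_target, mre_target = mre_target,
            overlap_weight = overlap_weight,
            gap_penalty_rate = gap_penalty_rate,
            min_score = min_score, min_length = as.integer(min_length),
            min_ref_samples = as.integer(min_ref_samples),
            merge_gap = as.integer(merge_gap))
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("detection_params: all parameters must be single positive numbers; bad: ",
         paste(bad, collapse = ", "))
  structure(p, class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("IM detection parameters\n")
  cat(sprintf("  normalization targets : MeDIP %.3g, MRE %.3g\n",
              x$medip_target, x$mre_target))
  cat(sprintf("  score                 : w = %g, lambda = %g /bp\n",
              x$overlap_weight, x$gap_penalty_rate))
  cat(sprintf("  cutoffs               : min_score = %g, min_length = %d bp\n",
              x$min_score, x$min_length))
  cat(sprintf("  reference set         : merge_gap = %d bp, >= %d samples\n",
              x$merge_gap, x$min_ref_samples))
  invisible(x)
}

#' Construct a per-CpG paired count track
#'
#' A `cpg_track` holds, for one sample, the MeDIP-Seq and MRE-Seq read
#' counts (or normalized densities) at every CpG, sorted by chromosome and
#' position. It is the substrate of the segmentation algorithm.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based position of
#'   the CpG cytosine), `medip`, `mre` (non-negative counts/densities).
#' @param sample_id Sample label.
#' @param sort Sort unsorted input (with a warning) instead of failing.
#' @return An object of class `cpg_track` with elements `sample_id`,
#'   `sites`, `medip_total`, `mre_total` (raw totals) and `normalized`.
#' @export
cpg_track <- function(sites, sample_id = "sample", sort = TRUE) {
  need <- c("chrom", "pos", "medip", "mre")
  if (!all(need %in% names(sites)))
    stop("cpg_track: sites must have columns ", paste(need, collapse = ", "))
  sites <- as.data.frame(sites)[need]
  sites$chrom <- as.character(sites$chrom)
  if (nrow(sites)) {
    if (any(sites$pos < 0)) stop("cpg_track: positions must be >= 0")
    if (any(sites$medip < 0) || any(sites$mre < 0))
      stop("cpg_track: counts must be >= 0")
    key <- order(sites$chrom, sites$pos)
    if (is.unsorted(key) || any(key != seq_len(nrow(sites)))) {
      if (!sort) stop("cpg_track: sites not sorted by (chrom, pos)")
      if (any(key != seq_len(nrow(sites)))) {
        warning("cpg_track: input not sorted by (chrom, pos); sorting")
        sites <- sites[key, , drop = FALSE]
        rownames(sites) <- NULL
      }
    }
    dup <- duplicated(sites[c("chrom", "pos")])
    if (any(dup))
      stop("cpg_track: duplicate CpG positions, e.g. ", sites$chrom[dup][1],
           ":", sites$pos[dup][1])
  }
  structure(list(sample_id = sample_id, sites = sites,
                 medip_total = sum(sites$medip), mre_total = sum(sites$mre),
                 normalized = FALSE),
            class = "cpg_track")
}

#' @export
print.cpg_track <- function(x, ...) {
  cat(sprintf("cpg_track '%s': %d CpGs on %d chromosome(s)\n",
              x$sample_id, nrow(x$sites), length(unique(x$sites$chrom))))
  cat(sprintf("  raw totals: MeDIP %.6g, MRE %.6g%s\n", x$medip_total,
              x$mre_total, if (x$normalized) "  (normalized)" else ""))
  invisible(x)
}

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a per-CpG paired count track
#'
#' Expects a headerless 4-column tab-separated file: `chrom pos medip mre`,
#' positions 0-based. Gzip-compressed files are accepted. Duplicate
#' positions are an error; unsorted input is sorted with a warning.
#'
#' @param path Path to the TSV (optionally .gz).
#' @param sample_id Sample label; defaults to the file name without
#'   extension.
#' @return A [cpg_track()].
#' @export
read_cpg_counts <- function(path,
                            sample_id = sub("\\.(tsv|txt|bedgraph)(\\.gz)?$",
                                            "", basename(path))) {
  if (!file.exists(path)) stop("read_cpg_counts: no such file: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(cpg_track(data.frame(chrom = character(), pos = integer(),
                                medip = numeric(), mre = numeric()),
                     sample_id = sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("read_cpg_counts: line ", which(nf != 4L)[1],
         " does not have 4 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  num <- suppressWarnings(list(pos = as.numeric(m[, 2]),
                               medip = as.numeric(m[, 3]),
                               mre = as.numeric(m[, 4])))
  for (fld in names(num)) {
    bad <- which(is.na(num[[fld]]))
    if (length(bad))
      stop("read_cpg_counts: line ", bad[1], ": non-numeric ", fld,
           " value '", m[bad[1], match(fld, names(num)) + 1L], "'")
  }
  cpg_track(data.frame(chrom = m[, 1], pos = num$pos, medip = num$medip,
                       mre = num$mre, stringsAsFactors = FALSE),
            sample_id = sample_id)
}

#' Write a per-CpG paired count track
#'
#' @param track A [cpg_track()].
#' @param path Output path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
write_cpg_counts <- function(track, path) {
  stopifnot(inherits(track, "cpg_track"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(track$sites, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize a track to fixed library-size targets
#'
#' Scales each assay so its total equals the target (defaults 50 M MeDIP,
#' 35 M MRE). Normalized densities are real-valued; no re-rounding is done,
#' which would distort low counts. Within-assay ratios are preserved.
#'
#' @param track A [cpg_track()] with positive totals in both assays.
#' @param params A [detection_params()].
#' @return The track with scaled densities and `normalized = TRUE`; the
#'   stored `medip_total`/`mre_total` remain the raw totals.
#' @export
normalize_track <- function(track, params = detection_params()) {
  stopifnot(inherits(track, "cpg_track"))
  if (track$medip_total <= 0 || track$mre_total <= 0)
    stop("normalize_track: cannot normalize a track with zero total in ",
         "either assay")
  track$sites$medip <- track$sites$medip * (params$medip_target / track$medip_total)
  track$sites$mre <- track$sites$mre * (params$mre_target / track$mre_total)
  track$normalized <- TRUE
  track
}

as_region_df <- function(regions) {
  regions <- as.data.frame(regions)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions)))
    stop("regions must have columns chrom, start, end")
  regions$chrom <- as.character(regions$chrom)
  if (nrow(regions) && any(regions$start >= regions$end))
    stop("regions: start must be < end (0-based half-open)")
  regions
}

regions_to_granges <- function(regions) {
  regions <- as_region_df(regions)
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1L,
                                          end = regions$end))
}

#' Read genomic regions from BED
#'
#' BED3+ (0-based half-open). The BED name column maps to `sample_id` and
#' the score column to `score` when present.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `sample_id`,
#'   `score`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("read_regions: no such file: ", path)
  if (file.size(path) == 0L || !length(readLines(path, n = 1L)))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sample_id = character(),
                      score = numeric()))
  gr <- rtracklayer::import(path, format = "BED")
  md <- S4Vectors::mcols(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             sample_id = if ("name" %in% names(md))
               as.character(md$name) else NA_character_,
             score = if ("score" %in% names(md))
               as.numeric(md$score) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write genomic regions to BED
#'
#' Regions with a `score` (and optionally `sample_id` as the name column)
#' are written as BED6, otherwise BED3. Round-trips with [read_regions()].
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optional
#'   `sample_id`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  regions <- as_region_df(regions)
  gr <- regions_to_granges(regions)
  has_name <- "sample_id" %in% names(regions) && !all(is.na(regions$sample_id))
  has_score <- "score" %in% names(regions) && !all(is.na(regions$score))
  if (has_name || has_score) {
    S4Vectors::mcols(gr)$name <- if (has_name)
      as.character(regions$sample_id) else "."
    S4Vectors::mcols(gr)$score <- if (has_score) regions$score else 0
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
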