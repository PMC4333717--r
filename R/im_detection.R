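#' Per-CpG score increments for the maximum scoring segment caller
#'
#' Converts a normalized track into the signed score sequence scanned by
#' [find_im_segments()]. A CpG where both assays have signal rewards the
#' intermediate-methylation hypothesis; a CpG where only one assay has
#' signal punishes it; a silent CpG is neutral. Each CpG is additionally
#' charged a gap penalty proportional to its distance from the previous CpG
#' on the same chromosome.
#'
#' The per-CpG increment is
#' `+w * min(medip, mre)` when both densities are positive (co-occurring
#' signal is only as strong as the weaker assay),
#' `-w * max(medip, mre)` when exactly one is positive (a strong one-sided
#' signal is strong evidence for a fully methylated or fully unmethylated
#' state), and `0` when both are zero. The gap penalty is
#' `lambda * (pos_i - pos_{i-1})`, zero for the first CpG of a chromosome.
#'
#' @param track A normalized [cpg_track()]. If assay totals do not match
#'   the normalization targets in `params` a warning is emitted (scores are
#'   then on an uncalibrated scale).
#' @param params A [detection_params()].
#' @return data.frame with columns `chrom`, `pos`, `delta`, `gap_penalty`.
#' @export
score_deltas <- function(track, params = detection_params()) {
  stopifnot(inherits(track, "cpg_track"))
  s <- track$sites
  cur_medip <- sum(s$medip)
  cur_mre <- sum(s$mre)
  if (nrow(s) &&
      (abs(cur_medip - params$medip_target) > 1e-6 * params$medip_target ||
       abs(cur_mre - params$mre_target) > 1e-6 * params$mre_target))
    warning("score_deltas: track totals do not match normalization targets; ",
            "segment scores will not be on the calibrated scale")
  both <- s$medip > 0 & s$mre > 0
  one <- xor(s$medip > 0, s$mre > 0)
  delta <- numeric(nrow(s))
  delta[both] <- params$overlap_weight * pmin(s$medip[both], s$mre[both])
  delta[one] <- -params$overlap_weight * pmax(s$medip[one], s$mre[one])
  gap <- numeric(nrow(s))
  if (nrow(s) > 1L) {
    d <- diff(s$pos)
    first <- c(TRUE, s$chrom[-1L] != s$chrom[-nrow(s)])
    gap[-1L] <- params$gap_penalty_rate * d
    gap[first] <- 0
  }
  data.frame(chrom = s$chrom, pos = s$pos, delta = delta, gap_penalty = gap,
             stringsAsFactors = FALSE)
}

# Left-to-right scan over one chromosome's penalized deltas. A candidate
# opens when the running score rises above zero; within a candidate the
# running maximum and its (first) position are tracked; when the score
# falls back to <= 0 or the input ends, the segment [open, peak] is emitted
# and the scan resumes at peak + 1, so material after a peak is
# reconsidered. Equivalent to the disjoint maximal-scoring subsequences of
# the penalized sequence.
scan_segments <- function(net) {
  n <- length(net)
  starts <- integer(0); peaks <- integer(0); scores <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (net[i] > 0) {
      S <- 0; best <- 0; peak <- i; j <- i
      repeat {
        S <- S + net[j]
        if (S > best) { best <- S; peak <- j }
        if (S <= 0 || j == n) break
        j <- j + 1L
      }
      starts <- c(starts, i); peaks <- c(peaks, peak)
      scores <- c(scores, best)
      i <- peak + 1L
    } else {
      i <- i + 1L
    }
  }
  list(start = starts, peak = peaks, score = scores)
}

#' Find candidate IM segments by maximum scoring segment search
#'
#' Scans each chromosome's penalized score sequence (`delta - gap_penalty`)
#' left to right with a running score floored at zero between segments.
#' When the score returns to zero after initiating a candidate region, the
#' region's end is the position with the highest running score since the
#' start, and the segment's score is that maximum. The scan resumes after
#' the peak, so the output is the set of disjoint maximal-scoring
#' subsequences, sorted by position.
#'
#' @param deltas Output of [score_deltas()]; positions must be strictly
#'   increasing within each chromosome.
#' @param sample_id Optional sample label attached to the calls.
#' @return data.frame of calls: `chrom`, `start` (first CpG of the
#'   segment), `end` (peak CpG position + 1, half-open), `score`
#'   (= running-score maximum, always > 0), `peak_pos`, `n_cpgs` (CpGs from
#'   start through peak), `sample_id`, `state = "IM"`.
#' @export
find_im_segments <- function(deltas, sample_id = NA_character_) {
  need <- c("chrom", "pos", "delta", "gap_penalty")
  stopifnot(all(need %in% names(deltas)))
  out <- lapply(split(seq_len(nrow(deltas)), deltas$chrom), function(idx) {
    pos <- deltas$pos[idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("find_im_segments: positions must be strictly increasing ",
           "within each chromosome")
    seg <- scan_segments(deltas$delta[idx] - deltas$gap_penalty[idx])
    if (!length(seg$start)) return(NULL)
    data.frame(chrom = deltas$chrom[idx[1]],
               start = pos[seg$start],
               end = pos[seg$peak] + 1L,
               score = seg$score,
               peak_pos = pos[seg$peak],
               n_cpgs = seg$peak - seg$start + 1L,
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  calls <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE))) else NULL
  if (is.null(calls) || !nrow(calls))
    calls <- data.frame(chrom = character(), start = integer(),
                        end = integer(), score = numeric(),
                        peak_pos = integer(), n_cpgs = integer(),
                        stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  calls$sample_id <- rep(sample_id, nrow(calls))
  calls$state <- rep("IM", nrow(calls))
  calls
}

#' Shuffle paired counts across CpG positions
#'
#' Randomly reassigns the (MeDIP, MRE) count pairs to CpG positions,
#' keeping each pair together and leaving positions untouched. This is the
#' null model for cutoff calibration: it preserves the marginal count
#' distribution and the pairing, but destroys the positional clustering
#' that the segment caller detects.
#'
#' @param track A [cpg_track()].
#' @param seed Integer seed; identical seeds give identical shuffles.
#' @return The shuffled track (totals unchanged).
#' @export
shuffle_counts <- function(track, seed) {
  stopifnot(inherits(track, "cpg_track"))
  n <- nrow(track$sites)
  if (n < 2L) return(track)
  perm <- withr::with_seed(seed, sample.int(n))
  track$sites$medip <- track$sites$medip[perm]
  track$sites$mre <- track$sites$mre[perm]
  track
}

#' Filter IM calls by score and length
#'
#' @param calls Calls from [find_im_segments()].
#' @param min_score Minimum segment score (default 8.0).
#' @param min_length Minimum region length in bp (default 100).
#' @param enforce_length Apply the length cutoff? In the published
#'   procedure the length cutoff is applied when assembling the reference
#'   set, not per sample, hence `FALSE` by default.
#' @return The retained calls, original order preserved.
#' @export
apply_filters <- function(calls, min_score = 8.0, min_length = 100L,
                          enforce_length = FALSE) {
  keep <- calls$score >= min_score
  if (enforce_length) keep <- keep & (calls$end - calls$start) >= min_length
  calls[keep, , drop = FALSE]
}

#' Calibrate score/length cutoffs against paired-shuffled tracks
#'
#' Runs segment detection on the observed track and on `n_shuffles`
#' shuffled tracks ([shuffle_counts()]), then scans a grid of
#' `(min_score, min_length)` pairs. The estimated false-positive rate of a
#' grid point is the mean number of cutoff-passing calls per shuffled track
#' divided by the number of cutoff-passing observed calls. The
#' least-stringent pair with FPR below `target_fpr` is selected (candidates
#' ordered by `min_score` first, then `min_length`). If no grid point
#' qualifies the most stringent one is returned with `converged = FALSE`
#' and a warning.
#'
#' @param track Normalized [cpg_track()].
#' @param params [detection_params()].
#' @param n_shuffles Number of shuffles (published procedure used 1,000).
#' @param target_fpr Upper bound on the estimated FPR (default 0.01).
#' @param seed Integer seed; shuffle `i` uses `seed + i`.
#' @param score_grid,length_grid Candidate cutoffs.
#' @return Object of class `im_calibration`: `chosen_min_score`,
#'   `chosen_min_length`, `fpr_estimate`, `null_score_dist`,
#'   `null_length_dist` (pooled over shuffles), `observed_calls`, `grid`
#'   (per-point FPRs), `n_shuffles`, `seed`, `converged`.
#' @export
calibrate_cutoffs <- function(track, params = detection_params(),
                              n_shuffles = 1000L, target_fpr = 0.01,
                              seed = 1L,
                              score_grid = seq(1, 20, by = 0.5),
                              length_grid = c(0L, 100L, 200L)) {
  if (n_shuffles < 1L) stop("calibrate_cutoffs: n_shuffles must be >= 1")
  obs <- find_im_segments(score_deltas(track, params), track$sample_id)
  if (!nrow(obs))
    stop("calibrate_cutoffs: no segments detected in the observed track; ",
         "FPR is undefined")
  null_scores <- vector("list", n_shuffles)
  null_lens <- vector("list", n_shuffles)
  for (i in seq_len(n_shuffles)) {
    sh <- find_im_segments(score_deltas(shuffle_counts(track, seed + i),
                                        params))
    null_scores[[i]] <- sh$score
    null_lens[[i]] <- sh$end - sh$start
  }
  grid <- expand.grid(min_score = score_grid, min_length = length_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$min_score, grid$min_length), , drop = FALSE]
  obs_len <- obs$end - obs$start
  pass <- function(sc, ln, s, l) sum(sc >= s & ln >= l)
  grid$n_observed <- mapply(function(s, l) pass(obs$score, obs_len, s, l),
                            grid$min_score, grid$min_length)
  grid$mean_null <- mapply(function(s, l) {
    mean(vapply(seq_len(n_shuffles),
                function(i) pass(null_scores[[i]], null_lens[[i]], s, l),
                numeric(1)))
  }, grid$min_score, grid$min_length)
  grid$fpr <- ifelse(grid$n_observed > 0, grid$mean_null / grid$n_observed,
                     Inf)
  ok <- which(grid$fpr < target_fpr)
  converged <- length(ok) > 0L
  pick <- if (converged) ok[1] else nrow(grid)
  if (!converged)
    warning("calibrate_cutoffs: no grid point achieved FPR < ", target_fpr,
            "; returning the most stringent point (observed and shuffled ",
            "call distributions may be indistinguishable)")
  structure(list(chosen_min_score = grid$min_score[pick],
                 chosen_min_length = grid$min_length[pick],
                 fpr_estimate = grid$fpr[pick],
                 null_score_dist = unlist(null_scores),
                 null_length_dist = unlist(null_lens),
                 observed_calls = obs,
                 grid = grid, n_shuffles = as.integer(n_shuffles),
                 target_fpr = target_fpr, seed = seed,
                 converged = converged),
            class = "im_calibration")
}

#' @export
print.im_calibration <- function(x, ...) {
  cat(sprintf("IM cutoff calibration (%d shuffles, seed %d)\n",
              x$n_shuffles, x$seed))
  cat(sprintf("  chosen cutoffs : score >= %g, length >= %d bp\n",
              x$chosen_min_score, x$chosen_min_length))
  cat(sprintf("  estimated FPR  : %.4g (target < %g)%s\n", x$fpr_estimate,
              x$target_fpr, if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  observed calls : %d; shuffled calls pooled: %d\n",
              nrow(x$observed_calls), length(x$null_score_dist)))
  invisible(x)
}

#' Assemble a multi-sample reference IM set
#'
#' Pools per-sample IM calls, merges calls whose gap is at most `merge_gap`
#' bp (transitively, across samples), counts the distinct samples
#' contributing at least one call to each merged cluster, and retains
#' clusters supported by at least `min_samples` samples and at least
#' `min_length` bp long. Re-running on its own output returns it unchanged
#' (with `min_samples = 1`).
#'
#' @param per_sample_calls Named list of call data.frames (names are sample
#'   ids), or a single data.frame with a `sample_id` column.
#' @param merge_gap Maximum gap merged (bp).
#' @param min_samples Minimum distinct supporting samples.
#' @param min_length Minimum merged-region length (bp).
#' @return data.frame `chrom`, `start`, `end`, `support`, `state = "IM"`.
#' @export
build_reference_set <- function(per_sample_calls, merge_gap = 100L,
                                min_samples = 2L, min_length = 100L) {
  if (is.data.frame(per_sample_calls)) {
    pooled <- per_sample_calls
    if (!"sample_id" %in% names(pooled))
      stop("build_reference_set: data.frame input needs a sample_id column")
  } else {
    ids <- names(per_sample_calls)
    if (is.null(ids)) ids <- paste0("sample", seq_along(per_sample_calls))
    pooled <- do.call(rbind, lapply(seq_along(per_sample_calls), function(i) {
      x <- as_region_df(per_sample_calls[[i]])
      x$sample_id <- ids[i]
      x[c("chrom", "start", "end", "sample_id")]
    }))
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer(),
                      state = character(), stringsAsFactors = FALSE)
  if (is.null(pooled) || !nrow(pooled)) return(empty)
  gr <- regions_to_granges(pooled)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  support <- vapply(split(pooled$sample_id[S4Vectors::queryHits(hits)],
                          S4Vectors::subjectHits(hits)),
                    function(s) length(unique(s)), integer(1))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged),
                    support = as.integer(support[as.character(
                      seq_along(merged))]),
                    stringsAsFactors = FALSE)
  out <- out[out$support >= min_samples &
               (out$end - out$start) >= min_length, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$state <- if (nrow(out)) "IM" else character(0)
  out
}
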