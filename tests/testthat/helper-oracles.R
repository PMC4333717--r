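# Independent oracles used across the suite.

# Disjoint maximal-scoring subsequence decomposition by exhaustive
# search: find the contiguous interval with the maximum sum (ties: higher
# score, then shorter, then leftmost), record it, recurse on both sides.
# Independent of the package's linear scan.
oracle_max_segments <- function(net) {
  recurse <- function(lo, hi) {
    if (lo > hi) return(NULL)
    x <- net[lo:hi]
    n <- length(x)
    cs <- c(0, cumsum(x))
    # sums[e, s] = sum(x[s..e]); lower triangle (e >= s) is valid
    sums <- outer(cs[2:(n + 1)], cs[1:n], "-")
    sums[upper.tri(sums)] <- -Inf
    top <- max(sums)
    if (top <= 0) return(NULL)
    cand <- which(sums == top, arr.ind = TRUE)
    cand <- cand[order(cand[, 1] - cand[, 2], cand[, 2]), , drop = FALSE]
    e_rel <- cand[1, 1]; s_rel <- cand[1, 2]
    s_abs <- lo + s_rel - 1
    e_abs <- lo + e_rel - 1
    rbind(recurse(lo, s_abs - 1),
          data.frame(start = s_abs, end = e_abs, score = top),
          recurse(e_abs + 1, hi))
  }
  out <- recurse(1, length(net))
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(), score = numeric())
  rownames(out) <- NULL
  out
}

# Two-sided Fisher p by direct enumeration with choose(); sums the
# probabilities of all tables (margins fixed) at most as probable as the
# observed one, with a small relative tolerance for floating-point ties.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  tot <- m + n
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x)
    choose(m, x) * choose(n, k - x) / choose(tot, k), numeric(1))
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Random delta/gap sequence on one chromosome for segmentation tests.
random_deltas <- function(n, seed, chrom = "chrT") {
  withr::with_seed(seed, {
    pos <- cumsum(sample(2:200, n, replace = TRUE))
    delta <- stats::rnorm(n, 0, 3)
    gap <- c(0, 0.01 * diff(pos))
    data.frame(chrom = chrom, pos = pos, delta = delta, gap_penalty = gap,
               stringsAsFactors = FALSE)
  })
}

# Minimal track constructor for hand-built fixtures.
toy_track <- function(pos, medip, mre, chrom = "chr1", sample_id = "toy") {
  cpg_track(data.frame(chrom = chrom, pos = pos, medip = medip, mre = mre),
            sample_id = sample_id)
}

# Params whose normalization targets equal the track totals, so synthetic
# counts are already on the calibrated scale and no advisory fires.
params_for_track <- function(track, ...) {
  detection_params(medip_target = track$medip_total,
                   mre_target = track$mre_total, ...)
}
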