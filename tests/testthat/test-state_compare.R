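test_that("call_state_regions applies the 75%-of-CpGs read rules", {
  # 4 CpGs: 3 unmethylated-pattern (mre>=4, medip=0), 1 mixed
  tr <- toy_track(pos = c(10, 20, 30, 40),
                  medip = c(0, 0, 0, 2), mre = c(4, 6, 5, 3))
  regions <- data.frame(chrom = "chr1", start = 0L, end = 50L)
  expect_equal(call_state_regions(tr, regions)$state, "unmethylated")

  tr_m <- toy_track(pos = c(10, 20, 30, 40),
                    medip = c(4, 5, 9, 4), mre = c(0, 0, 0, 0))
  expect_equal(call_state_regions(tr_m, regions)$state, "methylated")

  tr_both <- toy_track(pos = c(10, 20, 30, 40),
                       medip = c(4, 5, 9, 4), mre = c(1, 2, 1, 1))
  expect_equal(call_state_regions(tr_both, regions)$state, "neither")

  # 2 of 4 qualifying CpGs is below the 75% fraction
  tr_half <- toy_track(pos = c(10, 20, 30, 40),
                       medip = c(0, 0, 3, 2), mre = c(4, 6, 3, 3))
  expect_equal(call_state_regions(tr_half, regions)$state, "neither")

  empty_region <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  expect_warning(out <- call_state_regions(tr, empty_region), "no CpGs")
  expect_equal(out$state, "neither")
})

test_that("rpkm is the closed-form reads/kb/million and validates inputs", {
  expect_equal(rpkm(10, 1000, 1e6), 10.0)
  expect_equal(rpkm(0, 1000, 1e6), 0.0)
  expect_equal(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6) / 2)
  expect_equal(rpkm(7, 350, 3e7), 7 * 1e9 / (350 * 3e7))
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "total")
})

test_that("bin_signal_profile tiles the +/-5 kb window into 100 bp bins", {
  regions <- data.frame(chrom = "chr1", start = 9800L, end = 10200L)
  # region centre 10000; first bin [5000,5100)
  reads <- data.frame(chrom = "chr1",
                      start = c(5000L, 5050L, 9990L, 20000L),
                      end = c(5060L, 5130L, 10010L, 20100L))
  prof <- bin_signal_profile(regions, reads, total_reads = 1e6)
  expect_equal(ncol(prof$matrix), 100)
  expect_equal(prof$bin_offsets[1], -5000)
  # read midpoints 5030 and 5090 land in bin 1; 10000 in bin 51;
  # 20050 is outside the window
  expect_equal(prof$matrix[1, 1], rpkm(2, 100, 1e6))
  expect_equal(prof$matrix[1, 51], rpkm(1, 100, 1e6))
  expect_equal(sum(prof$matrix > 0), 2)
  # conservation: row sum recovers the in-window read count
  expect_equal(sum(prof$matrix[1, ]) * 100 * 1e6 / 1e9, 3)
})

test_that("profile means and sems summarise across regions", {
  regions <- data.frame(chrom = "chr1",
                        start = c(9800L, 49800L), end = c(10200L, 50200L))
  reads <- data.frame(chrom = "chr1", start = c(9990L, 49990L, 49890L),
                      end = c(10010L, 50010L, 49910L))
  prof <- bin_signal_profile(regions, reads, total_reads = 1e6)
  expect_equal(prof$bin_mean, colMeans(prof$matrix))
  expect_equal(dim(prof$matrix), c(2, 100))
  in_window <- sum(prof$matrix) * 100 * 1e6 / 1e9
  expect_equal(in_window, 3)
})

test_that("gene association uses nearest-edge distance within 10 kb", {
  regions <- data.frame(chrom = "chr1", start = 57800L, end = 58200L)
  tss <- data.frame(transcript_id = c("near", "far", "inside"),
                    chrom = "chr1", tss = c(50000L, 47799L, 57900L))
  pairs <- associate_regions_to_genes(regions, tss)
  expect_setequal(pairs$transcript_id, c("near", "inside"))
  expect_equal(pairs$distance[pairs$transcript_id == "near"], 7800)
  expect_equal(pairs$distance[pairs$transcript_id == "inside"], 0)
  # nearest edge exactly 10001 bp away is excluded
  expect_equal(57800 - 47799, 10001)
  expect_false("far" %in% pairs$transcript_id)
})

test_that("exon association uses interval distance within 1 kb", {
  regions <- data.frame(chrom = "chr1", start = 5000L, end = 5200L)
  exons <- data.frame(exon_id = c("e_near", "e_inside", "e_far"),
                      transcript_id = "tx1", chrom = "chr1",
                      start = c(5700L, 5100L, 6800L),
                      end = c(5900L, 5150L, 7000L))
  pairs <- associate_regions_to_exons(regions, exons)
  expect_setequal(pairs$exon_id, c("e_near", "e_inside"))
  expect_equal(pairs$distance[pairs$exon_id == "e_near"], 501)
  expect_equal(pairs$distance[pairs$exon_id == "e_inside"], 0)
})

test_that("relative exon expression is the exon/transcript RPKM ratio", {
  expect_equal(relative_exon_expression(5, 5), 1.0)
  expect_equal(relative_exon_expression(0, 5), 0.0)
  expect_warning(out <- relative_exon_expression(c(1, 2), c(4, 0)),
                 "excluded")
  expect_equal(out, c(0.25, NA))
})

test_that("group_rank_test matches exact enumeration for small groups", {
  # 3 vs 3, fully separated: smallest attainable two-sided p is 2/20
  expect_equal(group_rank_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  # enumeration oracle over all choose(n+m, n) assignments, 4 vs 3
  a <- c(0.3, 2.2, 4.1, 1.7); b <- c(5.5, 6.1, 0.9)
  pooled <- c(a, b)
  w_obs <- sum(rank(pooled)[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(7, 4)
  w_all <- apply(combos, 2, function(ix)
    sum(rank(pooled)[ix]) - 4 * 5 / 2)
  m <- length(w_all)
  p_oracle <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(group_rank_test(a, b), p_oracle)
  # identical groups: approximation branch (ties), p effectively 1
  expect_gte(group_rank_test(rep(1:5, 2), rep(1:5, 2)), 0.99)
  # shift invariance
  expect_equal(group_rank_test(a + 100, b + 100), group_rank_test(a, b))
  expect_error(group_rank_test(numeric(0), 1:3), "empty")
})

test_that("distance matrices satisfy the metric conventions", {
  bin <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0),
               s3 = c(0, 0, 1, 1), s4 = c(1, 0, 1, 0))
  d <- sample_distance_matrix(bin, "jaccard")
  expect_equal(d["s1", "s2"], 0)        # identical feature sets
  expect_equal(d["s1", "s3"], 1)        # disjoint feature sets
  expect_equal(d["s1", "s4"], 1 - 1 / 3)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 4), rownames(bin)))
  expect_error(sample_distance_matrix(matrix(c(0, 2, 1, 1), 2), "jaccard"),
               "binary")

  cnt <- rbind(s1 = c(4, 2, 0), s2 = c(4, 2, 0), s3 = c(1, 5, 2))
  dc <- sample_distance_matrix(cnt, "canberra")
  expect_equal(dc["s1", "s2"], 0)
  expect_equal(dc["s1", "s3"], 3 / 5 + 3 / 7 + 1)
  expect_equal(dc, t(dc))
  # agrees with stats::dist when no feature is zero in both samples
  pos <- withr::with_seed(5, matrix(rexp(12) + 0.1, nrow = 3,
                                    dimnames = list(paste0("s", 1:3), NULL)))
  expect_equal(as.matrix(stats::dist(pos, method = "canberra")),
               sample_distance_matrix(pos, "canberra"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("average_linkage_tree clusters identical samples first", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1))
  tree <- average_linkage_tree(sample_distance_matrix(m, "jaccard"))
  expect_s3_class(tree, "hclust")
  expect_equal(tree$method, "average")
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first, c("a", "b"))
})

test_that("overlap_enrichment detects self-overlap and calibrates on random placement", {
  universe <- data.frame(chrom = "chr1",
                         pos = seq(0L, 99950L, by = 50L))
  set_b <- data.frame(chrom = "chr1",
                      start = seq(0L, 9000L, by = 1000L),
                      end = seq(200L, 9200L, by = 1000L))
  res_self <- overlap_enrichment(set_b, set_b, universe,
                                 n_permutations = 200L, seed = 3L)
  expect_gt(res_self$fold_enrichment, 1)
  expect_lt(res_self$empirical_p, 0.05)
  expect_equal(res_self$observed,
               sum(universe$pos %% 1000 < 200 & universe$pos < 9200))

  # a set placed uniformly at random should show fold ~ 1
  set_a <- withr::with_seed(8, {
    anchor <- sample(universe$pos, 10)
    data.frame(chrom = "chr1", start = anchor, end = anchor + 200L)
  })
  res_rand <- overlap_enrichment(set_a, set_b, universe,
                                 n_permutations = 500L, seed = 4L)
  ci <- stats::quantile(res_rand$null, c(0.025, 0.975))
  expect_gte(res_rand$observed, ci[[1]])
  expect_lte(res_rand$observed, ci[[2]])

  expect_error(overlap_enrichment(set_a, set_b, universe,
                                  n_permutations = 0L), "permutations")
  expect_error(overlap_enrichment(set_a[0, ], set_b, universe), "empty")
})

test_that("expression ordering follows methylation state on the synthetic fixture", {
  fx <- simulate_expression_fixture(n_per_group = 60L, seed = 2L)
  pairs <- associate_regions_to_genes(fx$regions, fx$tss_table)
  expr <- merge(merge(pairs, fx$regions[c("region_id", "state")]),
                fx$expression)
  grp <- split(expr$rpkm, expr$state)
  expect_gt(mean(grp$unmethylated), mean(grp$IM))
  expect_gt(mean(grp$IM), mean(grp$methylated))

  epairs <- associate_regions_to_exons(fx$regions, fx$exon_table)
  expect_equal(nrow(epairs), nrow(fx$regions))
  rel <- relative_exon_expression(fx$exon_expression$R_e,
                                  fx$exon_expression$R_t)
  rgrp <- split(rel, fx$regions$state)
  expect_gt(mean(rgrp$methylated), mean(rgrp$IM))
  expect_gt(mean(rgrp$IM), mean(rgrp$unmethylated))
})
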