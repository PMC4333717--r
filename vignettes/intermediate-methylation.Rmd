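---
title: "Calling intermediate methylation from paired MeDIP/MRE-Seq: model and design notes"
author: "imseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling intermediate methylation from paired MeDIP/MRE-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imseg)
```

## The measurement model

Two complementary assays observe each CpG. MeDIP-Seq immunoprecipitates
methylated fragments, so its read density at a CpG grows with the
methylated fraction of the molecules covering it. MRE-Seq digests with
methylation-sensitive restriction enzymes, so its reads arise only from
*unmethylated* sites. In a mostly bimodal methylome the two signals are
mutually exclusive; CpGs where both assays report substantial signal are
in an intermediate methylation (IM) state — a mixture of methylated and
unmethylated molecules, whether across cells, across alleles, or both.

`imseg` treats the per-sample input as a `cpg_track`: one row per CpG
(0-based position of the C on the + strand; strand is not modelled
because the assays are strand-collapsed upstream), with MeDIP and MRE
counts assumed deduplicated and mapping-quality filtered before they
reach this package. Counts are library-size normalized to fixed targets
(defaults 50 M MeDIP, 35 M MRE) so that segment scores — and the score
cutoff — are comparable across samples. Normalized densities stay
real-valued; re-rounding would distort low counts.

## The segmentation score

No closed-form likelihood links the two assays, so the caller uses an
additive score designed to be on the read-count scale:

* both assays positive: `+w * min(medip, mre)` — co-occurring signal is
  only as strong as the weaker assay;
* exactly one positive: `-w * max(medip, mre)` — a strong one-sided
  signal is strong evidence for a fully methylated or fully unmethylated
  state;
* both zero: 0;
* every CpG is charged `lambda * gap` for the distance (bp) to the
  previous CpG on the chromosome, so sparse stretches cannot sustain a
  region on weak evidence.

Defaults are `w = 1` (scores stay in normalized read-count units) and
`lambda = 0.01`/bp (100 bp of gap costs one score unit, matching the
100 bp merge scale used downstream). Both are exposed in
`detection_params()`; they are conventions of this implementation, not
published constants.

The caller (`find_im_segments()`) scans each chromosome once: a running
score, floored at zero between segments, opens a candidate when it turns
positive; the candidate's end is the CpG with the highest running score
since the start (first such position on exact ties), and the scan resumes
immediately after that peak so trailing positive material can seed the
next segment. The emitted segments are exactly the disjoint
maximal-scoring subsequences of the penalized score sequence; the test
suite verifies this equivalence against an exhaustive recursive-argmax
oracle on a thousand random sequences, and recomputes every call's score
independently as the start-to-peak sum. Segments never span chromosome
boundaries, and coordinates are 0-based half-open with `end = peak + 1`.

## Cutoff calibration against paired shuffles

How large must a segment score be before it is believable? The null model
keeps everything about the data except positional clustering: the
(MeDIP, MRE) pairs are randomly reassigned to the existing CpG positions
(`shuffle_counts()`, pairing preserved, totals conserved). Detection runs
on the observed track and on each shuffled track; for every candidate
cutoff pair on a grid (score 1–20 in steps of 0.5 × length
{0, 100, 200} bp) the estimated false-positive rate is

> mean over shuffles of the number of cutoff-passing calls, divided by
> the number of cutoff-passing observed calls.

`calibrate_cutoffs()` returns the least stringent pair with FPR below the
1% target, ordering candidates by score first — the scalar-ratio FPR is
this package's concretisation of "compare the shuffled and observed score
and length distributions". When nothing on the grid qualifies (e.g. the
observed track is itself noise), the most stringent point is returned
with `converged = FALSE` and a warning rather than an arbitrary pass.
The published procedure used 1,000 shuffles; the tests and the
acceptance script use 100, which stabilises the FPR estimate to well
inside the 1% bound at the simulated track size while keeping runtimes
in seconds.

Per-sample calls are filtered by score only (`apply_filters()`,
`enforce_length = FALSE`); the length cutoff applies when the
multi-sample reference set is assembled (`build_reference_set()`: merge
calls within 100 bp across samples, keep clusters supported by ≥ 2
distinct samples and ≥ 100 bp long). Support is defined by membership in
the merged cluster — whether the original calls overlapped pairwise is
not re-checked, which is the natural reading when merging is transitive.
Assembly is idempotent on its own output.

## Allele-specific versus allele-independent methylation

IM can reflect one methylated and one unmethylated allele (ASM) or a
mixture unrelated to genotype (AIM). At a candidate heterozygous SNP the
package tabulates reads by allele and assay. The rules, with defaults in
`allelic_params()`:

* **heterozygosity**: ≥ 9 reads in each assay, ≤ 100 MRE reads (PCR-bias
  guard), and each allele carried by ≥ 30% of the reads of *at least one*
  assay. The per-allele reading matters: at a true ASM SNP each assay is
  nearly pure for opposite alleles, so demanding both alleles within one
  assay would reject exactly the SNPs of interest.
* **ASM**: MeDIP major-allele fraction ≥ 75%, MRE fraction of the
  *opposite* allele ≥ 75%, and two-sided Fisher's exact *P* < 0.01 on the
  2×2 assay×allele table. The cross-assay table is used because its
  p-value directly measures allele segregation between assays — the ASM
  phenomenon; per-assay tables against an expected 50/50 would need an
  external genotype model.
* **AIM**: neither assay's major fraction above 70% (exact 50/50 ties
  count as 0.5) and Fisher *P* > 0.01.

The 70%/75% gap plus the opposite p-value conditions make ASM and AIM
mutually exclusive by construction, and the classification is invariant
to swapping the ref/alt labels. A region is labelled ASM when it holds
≥ 2 ASM SNPs and no AIM SNPs (AIM symmetrically); regions with both are
ignored as ambiguous. `fisher_exact_2x2()` sums hypergeometric
probabilities of tables at most as probable as the observed one (relative
tie tolerance 1e-7, as in `stats::fisher.test`, against whose p-values it
is also cross-checked); dbSNP filtering is left to the caller.

## Downstream comparisons

* `call_state_regions()` labels a region unmethylated when ≥ 75% of its
  CpGs individually carry ≥ 4 MRE reads and zero MeDIP reads (methylated
  symmetrically). The per-CpG reading is the only one that makes "75% of
  CpGs" well-defined; the two per-CpG predicates are disjoint, so no
  region can earn both labels.
* `bin_signal_profile()` measures signal in 100 bp bins across ±5 kb from
  each region centre, assigning reads by midpoint (midpoint assignment
  avoids double counting) and reporting RPKM
  (`reads × 1e9 / (length × total)`), with per-bin mean ± SEM across
  regions. Binned means replace the GAM smoothing used for figure
  rendering in the original analysis — smoothing is presentation, not
  inference.
* Gene association uses nearest-edge distance to the TSS within 10 kb
  (0 when overlapping); exon association uses interval distance within
  1 kb. Distances are counted between covered bases of the half-open
  intervals, so adjacent features are 1 bp apart — consistent with the
  TSS arithmetic.
* Relative exon expression is the ratio `R_e / R_t` of exon to parent
  transcript RPKM; exons on silent transcripts are excluded. (The ratio
  form follows from the variable definitions; a log variant cannot be
  ruled out from the source, and would not change rank-based tests.)
* `group_rank_test()` is the two-sided Wilcoxon rank-sum test: exact up
  to 20 combined observations without ties, otherwise the tie-corrected
  normal approximation without continuity correction (identical groups
  give p = 1).
* `sample_distance_matrix()` offers Jaccard distance on binary
  IM-presence profiles and Canberra distance on count profiles
  (plain sum `Σ|x−y|/(|x|+|y|)` over features with a nonzero
  denominator — deliberately *not* rescaled by the number of
  contributing features, unlike `stats::dist`/`vegan::vegdist`), plus
  average-linkage clustering.
* `overlap_enrichment()` counts universe CpGs covered by both region
  sets, against a null that relocates the query set (lengths preserved)
  to random universe CpGs; it reports fold enrichment, a permutation
  p-value and a chi-squared statistic on the 2×2 coverage table.

## What the generator emulates — and what it does not

`simulation_config()` defaults define the synthetic study conditions used
throughout the tests:

```{r}
config <- simulation_config(seed = 1L)
truth <- simulate_genome(config)
truth
```

One chromosome of 6,000 CpGs with geometric inter-CpG gaps of mean 80 bp
(CpG-island-like clustering); 150 planted regions of 10 CpGs each,
interleaved M, IM, U (so each IM region is embedded in a bimodal
neighbourhood); independent Poisson counts per CpG with means
MeDIP/MRE = 8/0.1 (M), 0.1/8 (U), 4/4 (IM), 0.1/0.1 (background). The
rates sit on the normalized density scale, so pipelines on synthetic
tracks set the normalization targets to the track totals (identity
normalization) rather than inflating a toy genome to 50 M reads. Poisson
was chosen over negative binomial for transparency; overdispersion can be
layered on by callers but is off by default. Allelic draws use
Binomial(coverage, 0.95) purity for ASM (purity below 1 exercises the 75%
threshold realistically) and Binomial(coverage, 0.5) for AIM. Sub-seeds
are derived additively (genome: seed, counts: seed + 1, allelic:
seed + 2, shuffle *i*: seed + *i*) so each stage is independently
reproducible.

The generator does **not** model read-level artefacts (fragment-size or
GC bias, bisulfite errors), copy-number variation, overdispersion, or
correlated noise between assays. Passing recovery tests on this substrate
therefore demonstrates algorithmic correctness — that the caller finds
planted co-occurrence structure and the calibration controls false
positives under the stated null — not performance on real libraries,
where cutoffs must be recalibrated per sample.

Recovery scoring (`evaluate_recovery()`) matches calls to planted IM
regions by ≥ 50% reciprocal overlap (the standard DMR-benchmarking
criterion), optionally admitting calls whose two edges are both within a
slack; boundary error pools the absolute start and end differences of
matched pairs.

## Numerical choices and degenerate inputs

* Exact score ties at the running maximum resolve to the first peak
  position; with continuous normalized densities ties have measure zero.
* Normalization refuses tracks with a zero total in either assay;
  `score_deltas()` warns (not errors) when totals do not match the
  targets, since an uncalibrated scale invalidates the 8.0 cutoff but
  not the segmentation itself.
* Calibration errors out when the observed track yields no segments
  (the FPR ratio is undefined) and flags non-convergence instead of
  silently picking a cutoff.
* An all-zero 2×2 table and a region with no CpGs are rejected/flagged
  rather than scored; zero-variance allelic skews return `NA` with a
  warning rather than a spurious correlation.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
generator defaults (6,000 CpGs, 150 regions, 100 shuffles), the segmenter
oracle on 1,000 sequences of up to 50 CpGs, Fisher enumeration over all
2×2 tables with margins ≤ 15, 500 SNPs per allelic scheme, and 300 genes
per state group for the expression ordering — sizes chosen so the entire
suite completes in about a minute on one core while keeping every
statistical check comfortably powered.

## Known limitations

* The score/penalty form (`min`/`max` with weight `w`) matches the
  qualitative published description but is this package's choice; other
  monotone combinations would change absolute score values and hence the
  meaning of the calibrated cutoff.
* The FPR scalar compares passing-call *counts*; distribution-shape
  comparisons (e.g. KS distance between score distributions) are not
  implemented.
* Only the cross-assay Fisher table is offered for ASM; cohorts with
  external genotypes may prefer per-assay binomial tests.
* BED round-trips preserve `chrom/start/end/name/score`; richer state
  annotations travel in TSV outputs instead.
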