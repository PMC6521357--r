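---
title: "Histogram-feature DMR detection: models, parameters and design"
author: "histDMR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-feature DMR detection: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histDMR)
```

## The problem and the model

Whole genome bisulfite sequencing (WGBS) yields, for every cytosine, a
methylated read count `mc` and a total count `t`. Differentially
methylated regions (DMRs) between two treatment groups are runs of
cytosines with a consistent difference in methylation level `m = mc/t`.
Calling them well requires using three things at once: the spatial
correlation of methylation along the genome, the sampling noise implied
by read depth, and the biological variation between replicates.

histDMR treats the problem as supervised per-cytosine classification
followed by region assembly:

1. **Per-site statistics.** For each cytosine, coverage-weighted group
   mean levels `m1`, `m2` and a p-value for their difference. With at
   least two replicates per group the p-value comes from a weighted
   logistic regression of the group label on the replicate methylation
   levels — a chi-square likelihood-ratio test (1 df) of the full model
   against the intercept-only null, with observation weights
   `w(t) = 2/(1 + exp(-t/scale)) - 1` (scale = 10 reads) so that
   low-coverage replicates contribute little and zero-coverage ones
   nothing. Without replicates, a two-sided pooled two-proportion z-test
   on the group count sums is used.
2. **Bin values.** `b = |m1 - m2| * exp(1 - p)`: the methylation
   difference, boosted by up to a factor *e* when the difference is
   significant. The `b` track is smoothed per chromosome by a centred
   moving average over 3 cytosines and min-max scaled per chromosome to
   `[0, 1]`, giving `b_s`.
3. **Histogram features.** For every cytosine, a window of `w` cytosines
   (11 for CG, 51 for CH) votes into 10 bins of width 0.1: each window
   site contributes to the bin selected by its `b_s`
   (`min(floor(10 b_s), 9)`, so `b_s = 1` lands in the top bin) with
   weight `v = 1 - |l - l_c|/d` if its distance from the centre is below
   `d = 250` bp, else 0. The tally is normalised to sum to one; a window
   with no votes yields an all-zero sentinel row.
4. **Scoring.** A linear soft-margin SVM (hinge loss, cost 1,
   class-balanced weights) over the 10-bin features, with Platt-style
   logistic calibration of its decision values so scores lie in (0, 1).
5. **Assembly.** Cytosines with score > 0.1 seed candidate regions;
   candidates less than 500 bp apart merge, and non-candidate sites
   inside the span remain members. Boundaries are trimmed until `k = 3`
   consecutive member sites have raw bin value `b >= 0.1`; regions with
   no such run are discarded. Optional post-filters keep regions with
   more than `minSites` cytosines and an absolute regional methylation
   delta `|mean(m1) - mean(m2)|` above `minDelta`.

For `n >= 3` groups (time series), scores are computed for each of the
`choose(n, 2)` group pairs on the common site set and summed per
cytosine; the candidate cutoff scales to `0.1 * choose(n, 2)` so the
per-pair meaning of the default is preserved, refinement uses the
maximum `b` over pairs, and the output reports the mean level difference
and direction for every pair.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `w` | 11 (CG) / 51 (CH) | cytosines | feature window width |
| `d` | 250 | bp | maximum vote distance |
| `bins` | 10 | — | histogram resolution |
| `smoothSpan` | 3 | cytosines | spatial smoothing of `b` |
| weight `scale` | 10 | reads | depth at which a site reaches weight ~0.46 |
| `scoreCutoff` | 0.1 | — | candidate threshold on calibrated scores |
| `maxGap` | 500 | bp | candidate merge distance (strictly less than) |
| `k` | 3 | cytosines | boundary run length |
| `bThreshold` | 0.1 | — | boundary run threshold on raw `b` |
| `minSites`, `minDelta` | off (5 / 0.2 in the benchmark protocol) | — | post-filters |

The regional **delta** used by `minDelta` is the absolute value of the
mean signed difference, not the mean absolute difference (which is also
reported, as `meanAbsDiff`). The distinction does real work: background
noise produces sites whose differences are large but sign-incoherent, so
their regional mean cancels, while a true DMR is direction-consistent.

## Numerical choices

- The weighted logistic fit is a vectorised IRLS across all sites of a
  chromosome, with a ridge penalty `1e-4` on the slope only, an
  iteration cap of 50, per-site step halving, fitted probabilities
  clamped to `[1e-12, 1 - 1e-12]`, and the p-value floored at `1e-300`.
  The ridge keeps perfectly separated sites (common at strong DMRs)
  finite; the reported deviance difference is the unpenalised deviance
  evaluated at the penalised optimum, intercept unpenalised.
- Sites where one group carries zero total weight get `p = 1` with a
  warning — they carry no evidence but keep their place in the window
  structure. Pooled proportions of exactly 0 or 1 give `p = 1`.
- A group with a single replicate triggers the pooled z-test fallback
  (the LRT has no degrees of freedom to spare).
- Constant chromosome tracks min-max scale to all zeros; `b_s = 1`
  votes into bin 9 (clamped floor); windows truncate at chromosome ends
  rather than pad; the centre site votes with weight 1.
- Direction ties (`delta == 0`) are labelled `hyper` and flagged in the
  `tie` column.
- Platt calibration uses smoothed targets `(n+ + 1)/(n+ + 2)` and
  `1/(n- + 2)` so perfectly separated training decisions stay finite,
  and is fitted on the full training set at its natural class
  frequencies; the class-balanced subsample (cap 4000 rows) is used only
  for the SVM fit. Calibrating on the balanced subsample would roughly
  double background scores and with them the false-positive rate.

## The synthetic benchmark

`simulateBenchmark()` generates two-group beta-binomial genomes with
ground truth. DMR and non-DMR regions (defaults: lengths uniform in
500–2500 bp) alternate along one chromosome, separated by spacers of
1000–2000 bp — at least twice `maxGap`, so truth regions cannot merge
during calling. Cytosine positions follow geometric gaps (mean 100 bp);
coverage is negative-binomial (mean 10, size 5) per site and replicate.
Inside DMRs, per-site per-replicate levels are Beta(6, 1.5) in group 1
and Beta(1.5, 6) in group 2 (expected difference ~0.6). Class-1
background is a fixed 0.7 in both groups; class-2 background varies
along the genome with a per-site base level drawn from Beta(2, 2).

Two generator choices deserve emphasis:

- **Intra-DMR gaps are capped at 400 bp** (evenly spaced sites are
  inserted into larger gaps). With unmodified geometric gaps, about one
  DMR in ten would contain an inter-site gap above `maxGap` and would be
  unrecoverable as a single region *by construction*, confounding
  boundary-accuracy measurement with a layout artifact. This extends the
  same reasoning as the spacer rule.
- **Class-2 background replicates disperse around a shared base level**
  (`class2Mode = "dispersed"`: per-replicate levels Beta(20·µ, 20·(1-µ))
  around the site's base µ). Under the alternative literal reading —
  independent Beta(2, 2) draws per site *and replicate*
  (`class2Mode = "independent"`, available as a flag) — the two groups
  genuinely diverge at every background site (expected |m1 − m2| ≈ 0.17
  against a DMR effect of 0.6 with three replicates), a third of the
  background exceeds any usable score cutoff, and no region-accurate
  caller can simultaneously achieve high sensitivity and precision;
  near-ceiling class-2 operating points are unattainable in that
  regime for any method. The dispersed default keeps the background
  genuinely non-differential while exhibiting both along-genome level
  variation and replicate-level overdispersion — the textbook
  beta-binomial — and is measurably harder than class 1.
  `class2Mode = "shared"` (binomial reads around the base level) is the
  easy bound.

`simulateTrainingRegions()` emulates deriving labelled training regions
from orthogonal assays (differential chromatin-accessibility peaks,
differentially expressed genes) on a synthetic genome: strongly
differential candidates, nulls, and ~30% intermediates with graded
shifts (0.02–0.35) are generated; each candidate's realised mean
|m1 − m2| is then measured from the simulated counts and the
context-specific selection filters applied verbatim (CG: DMR if
diff > 0.3 and 500–2500 bp, non-DMR if diff < 0.1; CH: > 0.05 / < 0.02
in 500–5000 bp). Two aspects mirror real training data rather than the
benchmark: coverage defaults to 25x (curated training methylomes are
deep; at 10x the diff < 0.1 filter sits at the counting-noise floor and
rejects nearly every null region, skewing the class prior), and
candidate regions carry between-replicate biological variation (per-
region beta concentration drawn from {50, 20, 10}). The loose end of
that mix matters: regions that hover at the selection threshold and pass
it supply the *hard negatives* — moderate scaled bin values in
histogram bins 2–4 — without which the classifier assigns positive
weight to exactly the bins where noisy-background features live.

## What the tests show — and what they do not

The acceptance suite trains on a training genome (seed fixed), then
calls DMRs on disjoint benchmark genomes of 100 DMRs + 100 non-DMRs,
three replicates per group, coverage mean 10, averaging five random
simulations per class as the evaluation protocol prescribes; calls use the standard
post-filters (`minSites = 5`, `minDelta = 0.2`). At
these sizes the class-1 pipeline reaches TPR and PPV above 0.9 at 50%
reciprocal overlap, TPR above 0.7 at 80% overlap, a median boundary
displacement of about one cytosine per edge, zero calls on a ~50,000-
site zero-DMR genome, and a cytosine-level AUC above 0.9 when the model
is applied unchanged to a genome with halved site density and doubled
coverage. The full test suite runs in under a minute on one CPU.

The generator emulates — but does not reproduce — real WGBS: real CpG
spacing is heavily clustered (islands and deserts) rather than
geometric; real coverage tracks mappability; bisulfite conversion error
and strand asymmetries are absent; training labels here descend from the
generator's own effect-size grading rather than from an orthogonal
assay. Passing these tests therefore demonstrates the correctness and
internal consistency of the statistics, features, classifier and
assembly under controlled conditions, not field performance on any
particular organism.

Known limitations worth keeping in mind:

- Per-chromosome min-max scaling makes features depend on the
  chromosome-wide maximum of the smoothed `b` track. On a comparison
  with *no* real signal anywhere (two identically distributed groups),
  the scaling stretches pure noise over [0, 1] and scores become
  meaningless upstream of the post-filters; the delta filter is what
  keeps such comparisons clean (the label-shuffling analysis in the test
  suite exercises exactly this). In multi-group mode the same applies
  per pair, which is why a pair of truly identical groups contributes
  noise to the summed score.
- The pooled z-test is discrete: its null CDF steps around the uniform,
  so rejection rates are near-nominal rather than strictly
  conservative.
- The windowed features smear region edges by roughly `d` (250 bp) on
  each side; boundary refinement recovers most but not all of this,
  and at 10x coverage the raw-`b` threshold of 0.1 sits within the
  background noise band, so refinement trims softly.

## Reproducibility

Every stochastic component (layout, positions, coverage, levels, the
SVM's training subsample) is governed by a single integer seed;
`simulate -> train -> call` is bitwise reproducible. The command-line
wrapper records parameters, seed and package version in a JSON manifest
next to each output.
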