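# histDMR

Supervised detection of differentially methylated regions (DMRs) from
whole genome bisulfite sequencing (WGBS) count data, for epigenomics
analysts comparing two or more treatment groups — with or without
replicates, in CG or non-CG (CH) sequence context — who need accurate
DMR *boundaries* and a low false-positive rate.

## The method

For every cytosine with methylated / total read counts (mc, t), the
package computes group mean levels m₁, m₂ (coverage-weighted across
replicates, weights w(t) = 2·σ(t/10) − 1) and a p-value for their
difference: a weighted logistic-regression likelihood-ratio test
(χ², 1 df) when both groups have replicates, a pooled two-proportion
z-test otherwise. These combine into a bin value

  b = |m₁ − m₂| · e^(1−p),

which is smoothed (moving average, 3 cytosines) and min–max scaled per
chromosome to b_s ∈ [0, 1]. Each cytosine is then described by a 10-bin
histogram: the sites of a window of w cytosines (w = 11 for CG, 51 for
CH) vote into the bin selected by their b_s with a distance-tapered
weight v = 1 − |l − l_c|/d (d = 250 bp), and the tally is normalised to
sum to one. A linear soft-margin SVM with Platt-calibrated scores in
(0, 1) classifies each cytosine; sites scoring > 0.1 and lying < 500 bp
apart merge into preliminary regions whose boundaries are trimmed until
k = 3 consecutive member sites have b ≥ 0.1. Multi-group / time-series
designs sum the calibrated scores of all pairwise comparisons per
cytosine and report per-pair mean differences and directions.

Because labelled DMRs do not exist in nature, the package also ships a
beta-binomial simulator that generates benchmark genomes with ground
truth (class 1: fixed background; class 2: background varying along the
genome) and synthetic labelled training genomes emulating
training-region derivation from orthogonal assays, plus
reciprocal-overlap TPR/PPV evaluation. Everything needed to train,
call and score is self-contained.

## Worked example

Train a classifier on a synthetic labelled training genome, call DMRs
on a disjoint class-1 benchmark, and score the calls:

```r
library(histDMR)

model <- trainSyntheticModel(seed = 1)
model
#> TrainedModel (CG, v1.0): 10-bin linear classifier
#>   weights: -2.404 -3.396 -0.399 2.067 1.521 0.924 0.650 0.645 0.392 -0.000
#>   intercept 1.3991; calibration score = plogis(4.898*dec -1.339)

sim <- simulateBenchmark(SimConfig(simClass = 1, nDmr = 100, nNonDmr = 100),
                         seed = 2)
dmrs <- callPairwise(sim$group1, sim$group2, model,
                     CallParams(minSites = 5, minDelta = 0.2))
length(dmrs)
#> [1] 92
head(as.data.frame(dmrs), 3)
#>   seqnames start   end width strand nSites    meanM1    meanM2     delta
#> 1   chrSim  1502  2440   939      *     16 0.7787762 0.2448272 0.5339490
#> 2   chrSim  6925  8623  1699      *     19 0.8200386 0.2118759 0.6081626
#> 3   chrSim 14135 16663  2529      *     24 0.8290640 0.2145699 0.6144941
#>   meanAbsDiff meanScore direction   tie
#> 1   0.5478462 0.9613856     hyper FALSE
#> 2   0.6081626 0.9936629     hyper FALSE
#> 3   0.6209157 0.9879625     hyper FALSE

truth <- sim$truth[S4Vectors::mcols(sim$truth)$label == "DMR"]
tprPpv(truth, dmrs, thresholds = c(50, 80, 90))
#>   threshold  tpr       ppv nTruth nPred
#> 1        50 0.91 0.9891304    100    92
#> 2        80 0.70 0.7608696    100    92
#> 3        90 0.47 0.5108696    100    92
```

The negative weights on histogram bins 0–2 and positive weights on the
middle/upper bins are the classifier's learned picture of what
separates DMR windows (vote mass at high scaled differences) from
background windows. Each called region reports its cytosine count,
per-group mean levels, the regional delta |mean(m₁) − mean(m₂)|, the
mean calibrated score and the direction of change with respect to
group 1; here 91% of the simulated DMRs are recovered at 50% reciprocal
overlap with 99% precision, and 70% are recovered even when the call
must match the truth to within 80% reciprocal overlap.

A command-line wrapper with `simulate`, `train`, `pairwise`,
`timeseries` and `evaluate` subcommands lives at
`inst/scripts/histdmr.R`; each run writes a JSON manifest of its
parameters and seed.

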