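Package: histDMR
Title: Histogram-Based Detection of Differentially Methylated Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised detection of differentially methylated regions (DMRs)
    from whole genome bisulfite sequencing count data. Per-cytosine
    differential statistics (coverage-weighted logistic-regression likelihood
    ratio tests with replicates, pooled two-proportion z-tests without) are
    converted into distance-voted, p-value-weighted histogram features, scored
    with a calibrated linear support vector machine, and assembled into
    boundary-refined DMRs for pairwise and multi-group/time-series designs.
    Includes a beta-binomial read-count simulator for benchmark and training
    data with ground truth, and reciprocal-overlap TPR/PPV evaluation of
    called regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    data.table,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'methods-show.R'
    'io.R'
    'stats.R'
    'features.R'
    'model.R'
    'dmr.R'
    'sim.R'
    'eval.R'
    'cli.R'
    'histDMR-package.R'
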