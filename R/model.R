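#' Label candidate training regions by effect size and length
#'
#' Applies the context-specific selection rules for supervised training
#' regions. CG context: DMRs are candidates with mean absolute methylation
#' difference > 0.3 and length 500-2500 bp; non-DMRs have difference < 0.1
#' in the same size range. CH context: DMRs have difference > 0.05 and
#' length 500-5000 bp; non-DMRs difference < 0.02 in the same size range.
#' Candidates passing neither rule are dropped.
#'
#' @param candidates A \code{GRanges} with a \code{meanAbsDiff} metadata
#'   column (mean |m1 - m2| over contained cytosines).
#' @param context "CG" or "CH".
#' @return A \code{GRanges} with a \code{label} column ("DMR"/"nonDMR").
#' @export
selectTrainingRegions <- function(candidates, context = c("CG", "CH")) {
  context <- match.arg(context)
  stopifnot(is(candidates, "GRanges"),
            "meanAbsDiff" %in% colnames(mcols(candidates)))
  len <- BiocGenerics::width(candidates)
  diff <- mcols(candidates)$meanAbsDiff
  if (context == "CG") {
    sizeOk <- len >= 500 & len <= 2500
    isDmr <- sizeOk & diff > 0.3
    isNon <- sizeOk & diff < 0.1
  } else {
    sizeOk <- len >= 500 & len <= 5000
    isDmr <- sizeOk & diff > 0.05
    isNon <- sizeOk & diff < 0.02
  }
  keep <- isDmr | isNon
  if (!any(isDmr) && !any(isNon))
    stop("no candidate region passes either training filter")
  out <- candidates[keep]
  mcols(out)$label <- ifelse(isDmr[keep], "DMR", "nonDMR")
  BiocGenerics::sort(out)
}

#' Build a per-cytosine training set from labelled regions
#'
#' Computes site statistics and histogram features genome-wide (so windows
#' see flanking context beyond region edges), then collects the feature
#' rows of every cytosine inside a labelled region, labelled 1 (DMR) or 0
#' (non-DMR). Every cytosine is an independent training sample. A labelled
#' region containing no covered cytosines is skipped with a warning.
#'
#' @param group1,group2 Methylome(s) per treatment group (CG tables should
#'   already be strand-combined; [callPairwise()] does this automatically).
#' @param regions A \code{GRanges} with a \code{label} column
#'   ("DMR"/"nonDMR"), non-overlapping.
#' @param params A \linkS4class{FeatureParams}.
#' @param weightScale Depth scale for [coverageWeight()].
#' @return A list with \code{features} (matrix), \code{labels} (0/1),
#'   \code{region} (region index per row) and \code{stats}.
#' @export
buildTrainingSet <- function(group1, group2, regions,
                             params = FeatureParams(), weightScale = 10) {
  stopifnot(is(regions, "GRanges"))
  if (!length(regions)) stop("empty region list")
  if (!"label" %in% colnames(mcols(regions)))
    stop("regions must carry a 'label' metadata column")
  st <- siteStats(group1, group2, weightScale = weightScale)
  cf <- computeFeatures(st, params)
  siteGr <- GRanges(cf$stats$chrom, IRanges(cf$stats$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(siteGr, regions)
  hitRegions <- unique(subjectHits(ov))
  missed <- setdiff(seq_along(regions), hitRegions)
  if (length(missed))
    warning(length(missed), " labelled region(s) contain no covered ",
            "cytosines and were skipped")
  rows <- queryHits(ov)
  labels <- as.integer(mcols(regions)$label[subjectHits(ov)] == "DMR")
  if (length(unique(labels)) < 2L)
    stop("training set must contain both DMR and non-DMR cytosines")
  list(features = cf$features[rows, , drop = FALSE], labels = labels,
       region = subjectHits(ov), stats = cf$stats[rows, , drop = FALSE])
}

#' Train the calibrated linear DMR classifier
#'
#' Fits a linear soft-margin support vector machine (hinge loss, cost
#' \code{C}, class-balanced weights — positive cytosines are typically the
#' rarer class) on per-cytosine histogram features, then fits a Platt-style
#' one-dimensional logistic calibration of the decision values against the
#' labels so that prediction scores lie in (0, 1). For tractability the fit
#' uses a class-balanced random subsample of at most \code{maxRows}
#' cytosines (the feature distribution per class is what matters, not the
#' raw count); training is deterministic given \code{seed}.
#'
#' @param features Numeric matrix of histogram features.
#' @param labels Binary labels (1 = DMR cytosine).
#' @param params The \linkS4class{FeatureParams} used to build the features.
#' @param context "CG" or "CH".
#' @param C Soft-margin cost (default 1).
#' @param seed Integer seed for the subsample.
#' @param maxRows Subsample cap (default 4000).
#' @return A \linkS4class{TrainedModel}.
#' @export
trainModel <- function(features, labels, params = FeatureParams(),
                       context = "CG", C = 1, seed = 1L, maxRows = 4000L) {
  stopifnot(nrow(features) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to train")
  set.seed(as.integer(seed))
  perClass <- as.integer(maxRows) %/% 2L
  idx <- unlist(lapply(c(0L, 1L), function(cl) {
    i <- which(labels == cl)
    if (length(i) > perClass) sort(sample(i, perClass)) else i
  }))
  X <- features[idx, , drop = FALSE]
  y <- factor(labels[idx], levels = c(0L, 1L))
  cw <- length(y) / (2 * table(y))
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = c("0" = unname(cw["0"]),
                                      "1" = unname(cw["1"])))
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm's decision sign follows the order classes appear in the data;
  # orient so that positive decisions mean DMR
  dec <- drop(X %*% w) + b
  if (mean(dec[y == "1"]) < mean(dec[y == "0"])) {
    w <- -w; b <- -b; dec <- -dec
  }
  # Platt scaling on the full training set (natural class frequencies, not
  # the balanced subsample, so scores reflect the genome-wide class prior)
  # with smoothed targets (avoids divergence when the decision values
  # separate the classes perfectly)
  decAll <- drop(features %*% w) + b
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tgt <- ifelse(labels == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  cal <- suppressWarnings(
    glm(tgt ~ decAll, family = stats::quasibinomial()))
  calibA <- unname(coef(cal)[2]); calibB <- unname(coef(cal)[1])
  if (!is.finite(calibA) || calibA <= 0) {
    # degenerate calibration (e.g. constant decisions): fall back to the
    # identity map on the decision value
    calibA <- 1; calibB <- 0
  }
  new("TrainedModel", weights = as.numeric(w), intercept = as.numeric(b),
      calibA = calibA, calibB = calibB, params = params,
      context = context, version = MODEL_FORMAT_VERSION)
}

#' Train a classifier on a synthetic labelled training genome
#'
#' The package's canonical training protocol: simulate a labelled training
#' genome with [simulateTrainingRegions()], build the per-cytosine training
#' set, and fit the calibrated linear classifier. The default training
#' configuration uses a deep methylome (25x mean coverage) — training data
#' are curated, well-covered datasets, and at shallow depth the
#' region-selection filters sit at the counting-noise floor — with 100
#' strongly differential and 250 null candidate regions.
#'
#' @param seed Integer seed controlling the training genome and the fit.
#' @param context "CG" or "CH".
#' @param cfg \linkS4class{SimConfig} for the training genome.
#' @return A \linkS4class{TrainedModel}.
#' @export
trainSyntheticModel <- function(seed = 1L, context = c("CG", "CH"),
                                cfg = SimConfig(nDmr = 100L,
                                                nNonDmr = 250L,
                                                coverageMean = 25)) {
  context <- match.arg(context)
  tr <- simulateTrainingRegions(cfg, seed = seed, context = context)
  ts <- buildTrainingSet(tr$group1, tr$group2, tr$regions,
                         params = FeatureParams(context))
  trainModel(ts$features, ts$labels, params = FeatureParams(context),
             context = context, seed = seed)
}

#' Calibrated prediction scores for feature rows
#'
#' \code{score = plogis(calibA * (X w + intercept) + calibB)}; all-zero
#' sentinel rows score through the same formula (decision = intercept).
#'
#' @param model A \linkS4class{TrainedModel}.
#' @param features Matrix with \code{bins} columns (or a single row vector).
#' @return Scores in (0, 1).
#' @export
predictScores <- function(model, features) {
  stopifnot(is(model, "TrainedModel"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model@weights))
    stop("feature width ", ncol(features), " does not match model (",
         length(model@weights), " bins)")
  dec <- drop(features %*% model@weights) + model@intercept
  plogis(model@calibA * dec + model@calibB)
}
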