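#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

VALID_CONTEXTS <- c("CG", "CHG", "CHH", "CH")

#' Methylome: per-cytosine methylation counts for one sample
#'
#' Holds a single sample's cytosine-resolution methylation table as a
#' \linkS4class{GRanges} of width-1 sites (1-based positions) carrying the
#' sequence context and the methylated (\code{mc}) and total (\code{t}) read
#' counts as metadata columns. Sites are kept sorted by (chromosome,
#' position); sites with zero coverage are retained (they carry zero weight
#' in all downstream statistics, but preserve the positional structure used
#' by the windowed features).
#'
#' @slot sites A \code{GRanges} of width-1 ranges with metadata columns
#'   \code{context} (\code{CG}, \code{CHG} or \code{CHH}), \code{mc} and
#'   \code{t} (non-negative integers, \code{mc <= t}).
#' @slot sampleId Character scalar naming the sample.
#' @slot context Character scalar: the context the table was filtered to,
#'   one of \code{"CG"} or \code{"CH"} (\code{CH} = CHG + CHH analysed
#'   jointly) or a single non-CG context.
#'
#' @seealso [readMethylome()], [combineCGStrands()]
#' @export
setClass("Methylome",
  slots = c(sites = "GRanges", sampleId = "character", context = "character"))

setValidity("Methylome", function(object) {
  msg <- character()
  gr <- object@sites
  mc <- mcols(gr)
  if (!all(c("context", "mc", "t") %in% colnames(mc)))
    msg <- c(msg, "sites must carry metadata columns context, mc, t")
  else {
    if (any(mc$mc < 0) || any(mc$t < 0))
      msg <- c(msg, "read counts must be non-negative")
    if (any(mc$mc > mc$t))
      msg <- c(msg, "mc must not exceed t")
  }
  if (length(gr) && any(BiocGenerics::width(gr) != 1L))
    msg <- c(msg, "sites must be width-1 ranges")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@context) != 1L ||
      !object@context %in% VALID_CONTEXTS)
    msg <- c(msg, "context must be one of CG, CHG, CHH, CH")
  if (length(msg)) msg else TRUE
})

#' Feature hyperparameters for histogram features
#'
#' @slot w Window size in cytosines (odd, >= 3). Default 11 for CG, 51 for
#'   CH: non-CG sites are denser, so a wider window spans a comparable
#'   genomic extent.
#' @slot d Maximum vote distance in bp (default 250); sites farther than
#'   \code{d} from the window centre contribute nothing.
#' @slot bins Number of histogram bins (default 10, width 0.1 over [0,1]).
#' @slot smoothSpan Moving-average span in cytosines (odd, default 3).
#'
#' @export
setClass("FeatureParams",
  slots = c(w = "integer", d = "numeric", bins = "integer",
            smoothSpan = "integer"))

setValidity("FeatureParams", function(object) {
  msg <- character()
  if (object@w < 3L || object@w %% 2L == 0L)
    msg <- c(msg, "w must be odd and >= 3")
  if (object@d <= 0) msg <- c(msg, "d must be > 0")
  if (object@bins < 2L) msg <- c(msg, "bins must be >= 2")
  if (object@smoothSpan < 1L || object@smoothSpan %% 2L == 0L)
    msg <- c(msg, "smoothSpan must be odd and >= 1")
  if (length(msg)) msg else TRUE
})

#' @param context "CG" or "CH"; sets the default window size (11 or 51).
#' @param w,d,bins,smoothSpan Override individual hyperparameters.
#' @rdname FeatureParams-class
#' @export
FeatureParams <- function(context = c("CG", "CH"), w = NULL, d = 250,
                          bins = 10L, smoothSpan = 3L) {
  context <- match.arg(context)
  if (is.null(w)) w <- if (context == "CG") 11L else 51L
  new("FeatureParams", w = as.integer(w), d = as.numeric(d),
      bins = as.integer(bins), smoothSpan = as.integer(smoothSpan))
}

#' DMR calling parameters
#'
#' Thresholds controlling how scored cytosines are grouped into candidate
#' regions and how region boundaries are refined.
#'
#' @slot scoreCutoff Minimum calibrated prediction score for a cytosine to
#'   seed/extend a candidate region (default 0.1).
#' @slot maxGap Maximum distance in bp between consecutive candidate
#'   cytosines to be merged into the same preliminary region (default 500).
#' @slot k Number of consecutive member cytosines with bin value
#'   \code{b >= bThreshold} required at each refined boundary (default 3).
#' @slot bThreshold Bin-value threshold used in boundary refinement
#'   (default 0.1).
#' @slot minSites Optional post-filter: keep regions with more than this
#'   many sites (\code{NA} disables).
#' @slot minDelta Optional post-filter: keep regions whose absolute
#'   regional methylation delta \code{|mean(m1) - mean(m2)|} exceeds this
#'   (\code{NA} disables).
#'
#' @export
setClass("CallParams",
  slots = c(scoreCutoff = "numeric", maxGap = "numeric", k = "integer",
            bThreshold = "numeric", minSites = "numeric",
            minDelta = "numeric"))

setValidity("CallParams", function(object) {
  msg <- character()
  if (object@scoreCutoff < 0) msg <- c(msg, "scoreCutoff must be >= 0")
  if (object@maxGap <= 0) msg <- c(msg, "maxGap must be > 0")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (object@bThreshold < 0) msg <- c(msg, "bThreshold must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param scoreCutoff,maxGap,k,bThreshold,minSites,minDelta See slots.
#' @rdname CallParams-class
#' @export
CallParams <- function(scoreCutoff = 0.1, maxGap = 500, k = 3L,
                       bThreshold = 0.1, minSites = NA_real_,
                       minDelta = NA_real_) {
  new("CallParams", scoreCutoff = scoreCutoff, maxGap = maxGap,
      k = as.integer(k), bThreshold = bThreshold,
      minSites = as.numeric(minSites), minDelta = as.numeric(minDelta))
}

#' Simulation configuration for synthetic WGBS benchmarks
#'
#' Parameterises the beta-binomial benchmark generator. Two difficulty
#' classes are supported: in class 1 the non-DMR background has a fixed
#' methylation level (0.7 by default) so only DMRs vary between groups; in
#' class 2 the background level itself varies along the genome (per-site
#' base levels from Beta(2,2)), making DMRs harder to distinguish from
#' background; see \code{class2Mode} for how replicates relate to the
#' per-site base level.
#'
#' @slot simClass 1 or 2 (see above).
#' @slot nDmr,nNonDmr Numbers of true DMR and labelled non-DMR regions.
#' @slot repsPerGroup Replicates per treatment group (default 3).
#' @slot dmrBetaG1,dmrBetaG2 Beta parameters for per-site methylation levels
#'   inside DMRs, group 1 and group 2 (defaults (6, 1.5) and (1.5, 6):
#'   group 1 hyper-methylated, expected difference ~0.6).
#' @slot class1Background Fixed background level for class 1 (default 0.7).
#' @slot class2BackgroundBeta Beta parameters for class-2 background
#'   (default (2, 2)).
#' @slot siteGap Mean inter-cytosine gap in bp (geometric; default 100).
#' @slot coverageMean,coverageDispersion Negative-binomial read coverage:
#'   mean (default 10) and size/dispersion parameter (default 5).
#' @slot dmrLenRange,nonDmrLenRange Region length ranges in bp (defaults
#'   500-2500).
#' @slot spacerRange Inter-region spacer length range in bp (default
#'   1000-2000, i.e. at least twice the default merge gap so neighbouring
#'   truth regions cannot fuse during calling).
#' @slot class2Mode Class-2 background model: \code{"dispersed"} (default)
#'   draws one base level per site from \code{Beta(class2BackgroundBeta)},
#'   shared between groups, and adds replicate-level beta dispersion with
#'   concentration \code{class2Dispersion} (a beta-binomial background
#'   whose groups do not truly diverge); \code{"independent"} draws
#'   \code{Beta(class2BackgroundBeta)} independently per site and
#'   replicate (groups genuinely diverge by sampling); \code{"shared"}
#'   uses the per-site base level directly (binomial reads only).
#' @slot class2Dispersion Beta concentration of the replicate-level
#'   dispersion in dispersed mode (default 20).
#'
#' @export
setClass("SimConfig",
  slots = c(simClass = "integer", nDmr = "integer", nNonDmr = "integer",
            repsPerGroup = "integer", dmrBetaG1 = "numeric",
            dmrBetaG2 = "numeric", class1Background = "numeric",
            class2BackgroundBeta = "numeric", siteGap = "numeric",
            coverageMean = "numeric", coverageDispersion = "numeric",
            dmrLenRange = "numeric", nonDmrLenRange = "numeric",
            spacerRange = "numeric", class2Mode = "character",
            class2Dispersion = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!object@simClass %in% c(1L, 2L)) msg <- c(msg, "simClass must be 1 or 2")
  if (object@nDmr < 0L || object@nNonDmr < 0L ||
      object@nDmr + object@nNonDmr < 1L)
    msg <- c(msg, "region counts must be non-negative and sum to >= 1")
  if (object@repsPerGroup < 1L) msg <- c(msg, "repsPerGroup must be >= 1")
  for (nm in c("dmrBetaG1", "dmrBetaG2", "class2BackgroundBeta")) {
    v <- slot(object, nm)
    if (length(v) != 2L || any(v <= 0))
      msg <- c(msg, sprintf("%s must be two positive reals", nm))
  }
  if (object@class1Background < 0 || object@class1Background > 1)
    msg <- c(msg, "class1Background must be in [0,1]")
  if (object@siteGap < 1) msg <- c(msg, "siteGap must be >= 1")
  if (object@coverageMean <= 0 || object@coverageDispersion <= 0)
    msg <- c(msg, "coverage parameters must be positive")
  for (nm in c("dmrLenRange", "nonDmrLenRange", "spacerRange")) {
    v <- slot(object, nm)
    if (length(v) != 2L || v[1] > v[2] || v[1] <= 0)
      msg <- c(msg, sprintf("%s must be a valid positive range", nm))
  }
  if (!object@class2Mode %in% c("dispersed", "independent", "shared"))
    msg <- c(msg, "class2Mode must be dispersed, independent or shared")
  if (object@class2Dispersion <= 0)
    msg <- c(msg, "class2Dispersion must be positive")
  if (length(msg)) msg else TRUE
})

#' @param simClass,nDmr,nNonDmr,repsPerGroup,dmrBetaG1,dmrBetaG2 See slots.
#' @param class1Background,class2BackgroundBeta,siteGap See slots.
#' @param coverageMean,coverageDispersion,dmrLenRange,nonDmrLenRange See slots.
#' @param spacerRange,class2Mode,class2Dispersion See slots.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(simClass = 1L, nDmr = 2142L, nNonDmr = 2142L,
                      repsPerGroup = 3L, dmrBetaG1 = c(6, 1.5),
                      dmrBetaG2 = c(1.5, 6), class1Background = 0.7,
                      class2BackgroundBeta = c(2, 2), siteGap = 100,
                      coverageMean = 10, coverageDispersion = 5,
                      dmrLenRange = c(500, 2500),
                      nonDmrLenRange = c(500, 2500),
                      spacerRange = c(1000, 2000),
                      class2Mode = c("dispersed", "independent", "shared"),
                      class2Dispersion = 20) {
  class2Mode <- match.arg(class2Mode)
  new("SimConfig", simClass = as.integer(simClass), nDmr = as.integer(nDmr),
      nNonDmr = as.integer(nNonDmr), repsPerGroup = as.integer(repsPerGroup),
      dmrBetaG1 = dmrBetaG1, dmrBetaG2 = dmrBetaG2,
      class1Background = class1Background,
      class2BackgroundBeta = class2BackgroundBeta, siteGap = siteGap,
      coverageMean = coverageMean, coverageDispersion = coverageDispersion,
      dmrLenRange = as.numeric(dmrLenRange),
      nonDmrLenRange = as.numeric(nonDmrLenRange),
      spacerRange = as.numeric(spacerRange),
      class2Mode = class2Mode, class2Dispersion = class2Dispersion)
}

#' A trained, calibrated linear DMR classifier
#'
#' The per-cytosine classifier: a linear decision function over the
#' 10-bin histogram feature plus a Platt-style logistic calibration mapping
#' decision values to scores in (0,1), together with the feature
#' hyperparameters it was trained under.
#'
#' @slot weights Numeric vector of length \code{bins}: linear decision
#'   weights.
#' @slot intercept Decision-function intercept.
#' @slot calibA,calibB Logistic calibration: score = plogis(calibA * decision
#'   + calibB).
#' @slot params The \linkS4class{FeatureParams} used to build features.
#' @slot context "CG" or "CH".
#' @slot version Serialisation format version string.
#'
#' @export
setClass("TrainedModel",
  slots = c(weights = "numeric", intercept = "numeric", calibA = "numeric",
            calibB = "numeric", params = "FeatureParams",
            context = "character", version = "character"))

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (length(object@weights) != object@params@bins)
    msg <- c(msg, "weights length must equal the number of feature bins")
  for (nm in c("intercept", "calibA", "calibB"))
    if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
      msg <- c(msg, sprintf("%s must be a finite scalar", nm))
  if (!object@context %in% c("CG", "CH", "CHG", "CHH"))
    msg <- c(msg, "context must be CG, CH, CHG or CHH")
  if (length(msg)) msg else TRUE
})
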