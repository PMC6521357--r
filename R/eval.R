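#' Reciprocal overlap between two intervals
#'
#' The smaller of the two mutual overlap fractions,
#' \code{min(ov / len(a), ov / len(b))}, where \code{ov} is the overlap in
#' bp. Intervals are half-open \code{[start, end)}; intervals on different
#' chromosomes overlap by 0.
#'
#' @param aStart,aEnd,bStart,bEnd Interval bounds (bp, half-open;
#'   vectorised).
#' @param aChrom,bChrom Optional chromosome names.
#' @return Fractions in [0, 1].
#' @export
reciprocalOverlap <- function(aStart, aEnd, bStart, bEnd,
                              aChrom = NULL, bChrom = NULL) {
  if (any(aStart >= aEnd) || any(bStart >= bEnd))
    stop("intervals must have start < end")
  ov <- pmax(0, pmin(aEnd, bEnd) - pmax(aStart, bStart))
  frac <- pmin(ov / (aEnd - aStart), ov / (bEnd - bStart))
  if (!is.null(aChrom) && !is.null(bChrom))
    frac[aChrom != bChrom] <- 0
  frac
}

.roGRanges <- function(a, b) {
  reciprocalOverlap(BiocGenerics::start(a) - 1L, BiocGenerics::end(a),
                    BiocGenerics::start(b) - 1L, BiocGenerics::end(b),
                    as.character(GenomicRanges::seqnames(a)),
                    as.character(GenomicRanges::seqnames(b)))
}

#' TPR/PPV curves over a reciprocal-overlap grid
#'
#' At each overlap threshold \code{f} (percent), a truth region counts as
#' recovered if at least one prediction overlaps it reciprocally by
#' \code{>= f}; a prediction counts as true if at least one truth region
#' does. TPR = recovered truths / all truths; PPV = true predictions / all
#' predictions (0 when there are no predictions). Matching is many-to-one:
#' two fragments hitting one truth region count once in TPR but separately
#' in PPV.
#'
#' @param truth \code{GRanges} of true DMRs (sorted, non-overlapping).
#' @param predicted \code{GRanges} of called DMRs.
#' @param thresholds Percent reciprocal-overlap grid (default 50 to 100 by
#'   5).
#' @return A data.frame with columns \code{threshold}, \code{tpr},
#'   \code{ppv}, \code{nTruth}, \code{nPred}.
#' @export
tprPpv <- function(truth, predicted, thresholds = seq(50, 100, by = 5)) {
  stopifnot(is(truth, "GRanges"), is(predicted, "GRanges"))
  if (!length(truth)) stop("empty truth set")
  nT <- length(truth); nP <- length(predicted)
  if (!nP)
    return(data.frame(threshold = thresholds, tpr = 0, ppv = 0,
                      nTruth = nT, nPred = 0L))
  ov <- GenomicRanges::findOverlaps(truth, predicted)
  ro <- .roGRanges(truth[queryHits(ov)], predicted[subjectHits(ov)])
  vapplyThr <- function(f) {
    hit <- ro >= f / 100
    c(tpr = length(unique(queryHits(ov)[hit])) / nT,
      ppv = length(unique(subjectHits(ov)[hit])) / nP)
  }
  m <- vapply(thresholds, vapplyThr, c(tpr = 0, ppv = 0))
  data.frame(threshold = thresholds, tpr = m["tpr", ], ppv = m["ppv", ],
             nTruth = nT, nPred = nP)
}

#' Repeat a simulate-train-call benchmark over several seeds
#'
#' Runs \code{pipeline(cfg, seed)} — a closure returning
#' \code{list(truth, predicted)} — for \code{nSims} consecutive seeds and
#' summarises the per-threshold mean and standard deviation of the TPR and
#' PPV curves.
#'
#' @param cfg A \linkS4class{SimConfig} passed through to the pipeline.
#' @param pipeline Function \code{(cfg, seed) -> list(truth, predicted)}.
#' @param nSims Number of independent simulations (default 5).
#' @param seed First seed; runs use \code{seed, seed+1, ...}.
#' @param thresholds Percent reciprocal-overlap grid.
#' @return A data.frame with per-threshold \code{tprMean, tprSd, ppvMean,
#'   ppvSd} plus the per-run curves in attribute \code{"runs"}.
#' @export
replicateStudy <- function(cfg, pipeline, nSims = 5L, seed = 1L,
                           thresholds = seq(50, 100, by = 5)) {
  runs <- lapply(seq_len(nSims), function(s) {
    out <- pipeline(cfg, as.integer(seed) + s - 1L)
    truth <- out$truth
    if ("label" %in% colnames(mcols(truth)))
      truth <- truth[mcols(truth)$label == "DMR"]
    tprPpv(truth, out$predicted, thresholds)
  })
  tpr <- vapply(runs, function(r) r$tpr, numeric(length(thresholds)))
  ppv <- vapply(runs, function(r) r$ppv, numeric(length(thresholds)))
  tpr <- matrix(tpr, nrow = length(thresholds))
  ppv <- matrix(ppv, nrow = length(thresholds))
  sdRow <- function(m) if (ncol(m) > 1L) apply(m, 1, sd) else
    rep(0, nrow(m))
  out <- data.frame(threshold = thresholds,
                    tprMean = rowMeans(tpr),
                    tprSd = sdRow(tpr),
                    ppvMean = rowMeans(ppv),
                    ppvSd = sdRow(ppv))
  attr(out, "runs") <- runs
  out
}
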