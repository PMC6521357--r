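#' @importFrom stats pchisq pnorm plogis rbinom rbeta rnbinom rgeom runif
#'   quantile median sd glm coef binomial
NULL

#' Per-cytosine methylation level
#'
#' \code{mc / t}, defined as 0 when \code{t = 0} (such sites carry zero
#' coverage weight downstream, so the placeholder value is inert).
#'
#' @param mc,t Methylated and total read counts (vectorised).
#' @return Levels in [0, 1].
#' @export
methylationLevel <- function(mc, t) {
  if (any(mc < 0 | t < 0)) stop("counts must be non-negative")
  if (any(mc > t)) stop("mc must not exceed t")
  ifelse(t > 0, mc / t, 0)
}

#' Coverage weight from read depth
#'
#' A rescaled logistic in total read count:
#' \code{w(t) = 2 / (1 + exp(-t/scale)) - 1}. It is 0 at zero coverage,
#' strictly increasing, and saturates towards 1; with the default
#' \code{scale = 10} reads, a site at typical WGBS depth (~10x) gets weight
#' ~0.46 and a 30x site ~0.9.
#'
#' @param t Total read counts (vectorised).
#' @param scale Depth scale in reads (> 0, default 10).
#' @return Weights in [0, 1).
#' @export
coverageWeight <- function(t, scale = 10) {
  if (length(scale) != 1L || scale <= 0) stop("scale must be a positive scalar")
  if (any(t < 0)) stop("t must be non-negative")
  2 / (1 + exp(-t / scale)) - 1
}

#' Two-proportion z-test p-value for groups without replicates
#'
#' Two-sided pooled z-test for a difference in methylation proportion:
#' with pooled proportion \code{phat = (mc1+mc2)/(t1+t2)},
#' \code{z = (m1 - m2) / sqrt(phat (1-phat) (1/t1 + 1/t2))} and
#' \code{p = 2 (1 - Phi(|z|))}. Degenerate pooled proportions (0 or 1) give
#' \code{p = 1}; zero coverage in either group gives \code{p = 1} with a
#' warning (the site carries no evidence).
#'
#' @param mc1,t1,mc2,t2 Counts for the two groups (vectorised).
#' @return Two-sided p-values in [0, 1].
#' @export
pvalueSingle <- function(mc1, t1, mc2, t2) {
  if (any(mc1 > t1) || any(mc2 > t2)) stop("mc must not exceed t")
  if (any(c(mc1, t1, mc2, t2) < 0)) stop("counts must be non-negative")
  n <- max(length(mc1), length(mc2))
  mc1 <- rep_len(mc1, n); t1 <- rep_len(t1, n)
  mc2 <- rep_len(mc2, n); t2 <- rep_len(t2, n)
  p <- rep(1, n)
  zero <- t1 == 0 | t2 == 0
  if (any(zero))
    warning(sum(zero), " site(s) with zero coverage in a group: p set to 1")
  ok <- !zero
  if (any(ok)) {
    phat <- (mc1[ok] + mc2[ok]) / (t1[ok] + t2[ok])
    m1 <- mc1[ok] / t1[ok]
    m2 <- mc2[ok] / t2[ok]
    se2 <- phat * (1 - phat) * (1 / t1[ok] + 1 / t2[ok])
    z <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    pv <- ifelse(phat <= 0 | phat >= 1, 1, 2 * pnorm(-abs(z)))
    p[ok] <- pmax(pv, 1e-300)
  }
  p
}

# Vectorised ridge-stabilised weighted logistic likelihood-ratio test.
# L, Wt: nSites x nObs matrices of per-replicate methylation levels and
# coverage weights; y: per-observation binary group label. Ridge penalises
# the slope only; the reported deviance difference is unpenalised, evaluated
# at the penalised optimum. Returns list(p, stat, degenerate).
.wlogitLRTVec <- function(L, Wt, y, ridge = 1e-4, maxIter = 50L,
                          tol = 1e-12) {
  n <- nrow(L); R <- ncol(L)
  stopifnot(length(y) == R)
  eps <- 1e-12
  ymat <- matrix(y, n, R, byrow = TRUE)
  sw <- rowSums(Wt)
  sw1 <- rowSums(Wt[, y == 1, drop = FALSE])
  sw0 <- sw - sw1
  degenerate <- sw1 <= 0 | sw0 <= 0
  mu0 <- ifelse(sw > 0, sw1 / sw, 0.5)
  mu0 <- pmin(pmax(mu0, eps), 1 - eps)
  devNull <- -2 * (sw1 * log(mu0) + sw0 * log(1 - mu0))

  devAt <- function(b0, b1) {
    eta <- b0 + L * b1
    mu <- pmin(pmax(plogis(eta), eps), 1 - eps)
    -2 * rowSums(Wt * (ymat * log(mu) + (1 - ymat) * log(1 - mu)))
  }
  b0 <- log(mu0 / (1 - mu0)); b1 <- rep(0, n)
  devP <- devAt(b0, b1) + ridge * b1^2
  for (it in seq_len(maxIter)) {
    eta <- b0 + L * b1
    mu <- pmin(pmax(plogis(eta), eps), 1 - eps)
    v <- mu * (1 - mu)
    Wi <- Wt * v
    z <- eta + (ymat - mu) / v
    S0 <- rowSums(Wi); S1 <- rowSums(Wi * L)
    S2 <- rowSums(Wi * L * L) + ridge
    T0 <- rowSums(Wi * z); T1 <- rowSums(Wi * L * z)
    det <- S0 * S2 - S1 * S1
    ok <- det > 1e-300 & !degenerate
    nb0 <- ifelse(ok, (S2 * T0 - S1 * T1) / det, b0)
    nb1 <- ifelse(ok, (S0 * T1 - S1 * T0) / det, b1)
    # step-halve any site whose penalised deviance failed to decrease
    d0 <- nb0 - b0; d1 <- nb1 - b1
    newDevP <- devAt(nb0, nb1) + ridge * nb1^2
    bad <- which(ok & newDevP > devP + 1e-10)
    half <- 0L
    while (length(bad) && half < 12L) {
      d0[bad] <- d0[bad] / 2; d1[bad] <- d1[bad] / 2
      nb0[bad] <- b0[bad] + d0[bad]; nb1[bad] <- b1[bad] + d1[bad]
      subDev <- devAt(nb0, nb1)[bad] + ridge * nb1[bad]^2
      newDevP[bad] <- subDev
      bad <- bad[subDev > devP[bad] + 1e-10]
      half <- half + 1L
    }
    conv <- abs(devP - newDevP) < tol * (abs(newDevP) + 0.1)
    b0 <- nb0; b1 <- nb1; devP <- newDevP
    if (all(conv | !ok)) break
  }
  dev <- devP - ridge * b1^2
  stat <- pmax(devNull - dev, 0)
  p <- pmax(pchisq(stat, df = 1, lower.tail = FALSE), 1e-300)
  p[degenerate] <- 1
  list(p = p, stat = stat, degenerate = degenerate)
}

#' Weighted logistic-regression likelihood-ratio p-value (replicated groups)
#'
#' Fits a weighted logistic regression of the binary group label on the
#' per-replicate methylation level (observation weights = coverage weights),
#' and compares it against the intercept-only null by a chi-square
#' likelihood-ratio test with 1 degree of freedom. The slope carries a small
#' ridge penalty (default 1e-4) and iterations are capped at 50 so the fit
#' stays finite under perfect separation; the p-value is floored at 1e-300.
#'
#' If all weights are zero, or all the weight falls in one group, the site
#' carries no evidence and \code{p = 1} is returned with a warning.
#'
#' @param levels Per-replicate methylation levels in [0, 1].
#' @param labels Binary group labels (0/1, or a 2-level factor).
#' @param weights Non-negative per-replicate coverage weights.
#' @param ridge Ridge penalty on the slope.
#' @param maxIter Iteration cap.
#' @return A single p-value in [1e-300, 1].
#' @export
pvalueReplicates <- function(levels, labels, weights = rep(1, length(levels)),
                             ridge = 1e-4, maxIter = 50L) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  stopifnot(length(levels) == length(labels),
            length(weights) == length(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (min(sum(labels == 0), sum(labels == 1)) < 2L)
    stop("need >= 2 observations per group; use pvalueSingle otherwise")
  if (sum(weights[labels == 0]) <= 0 || sum(weights[labels == 1]) <= 0) {
    warning("a group carries zero total weight: p set to 1")
    return(1)
  }
  fit <- .wlogitLRTVec(matrix(levels, nrow = 1), matrix(weights, nrow = 1),
                       labels, ridge = ridge, maxIter = maxIter)
  fit$p[1]
}

# Align a list of Methylome objects onto the union of their (chrom, pos)
# keys. Returns list(chrom, pos, mc, t) with one matrix column per sample;
# sites absent from a sample get mc = t = 0.
.alignCounts <- function(methylomes) {
  tabs <- lapply(methylomes, function(m) {
    gr <- sites(m)
    data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = BiocGenerics::start(gr),
               mc = mcols(gr)$mc, t = mcols(gr)$t)
  })
  keys <- unique(data.table::rbindlist(
    lapply(tabs, function(x) x[, c("chrom", "pos")])))
  setorder(keys, chrom, pos)
  nS <- nrow(keys); nR <- length(tabs)
  mcM <- matrix(0L, nS, nR); tM <- matrix(0L, nS, nR)
  for (j in seq_len(nR)) {
    hit <- tabs[[j]][keys, on = c("chrom", "pos")]
    mcM[, j] <- ifelse(is.na(hit$mc), 0L, hit$mc)
    tM[, j] <- ifelse(is.na(hit$t), 0L, hit$t)
  }
  list(chrom = keys$chrom, pos = keys$pos, mc = mcM, t = tM)
}

#' Per-cytosine differential statistics for two groups
#'
#' Aligns the replicates of two treatment groups on the union of their
#' sites and computes, per cytosine: coverage-weighted group mean levels
#' \code{m1}, \code{m2}; and a p-value for the group difference — a weighted
#' logistic-regression likelihood-ratio test when both groups have at least
#' two replicates, otherwise a pooled two-proportion z-test on counts summed
#' within each group.
#'
#' @param group1,group2 A \linkS4class{Methylome} or list of them
#'   (replicates) per treatment group.
#' @param weightScale Depth scale for [coverageWeight()].
#' @param ridge,maxIter Passed to the weighted logistic fit.
#' @return A data.frame with columns \code{chrom, pos, m1, m2, p}, sorted by
#'   (chrom, pos).
#' @export
siteStats <- function(group1, group2, weightScale = 10, ridge = 1e-4,
                      maxIter = 50L) {
  if (is(group1, "Methylome")) group1 <- list(group1)
  if (is(group2, "Methylome")) group2 <- list(group2)
  n1 <- length(group1); n2 <- length(group2)
  stopifnot(n1 >= 1L, n2 >= 1L)
  al <- .alignCounts(c(group1, group2))
  .statsFromAligned(al, seq_len(n1), n1 + seq_len(n2),
                    weightScale = weightScale, ridge = ridge,
                    maxIter = maxIter)
}

# Group-vs-group statistics from pre-aligned count matrices; i1/i2 index
# the replicate columns of the two groups being compared.
.statsFromAligned <- function(al, i1, i2, weightScale = 10, ridge = 1e-4,
                              maxIter = 50L) {
  L <- ifelse(al$t > 0, al$mc / al$t, 0)
  W <- coverageWeight(al$t, scale = weightScale)
  m1 <- .groupMean(L, W, i1)
  m2 <- .groupMean(L, W, i2)
  if (min(length(i1), length(i2)) >= 2L) {
    cols <- c(i1, i2)
    y <- c(rep(0, length(i1)), rep(1, length(i2)))
    fit <- .wlogitLRTVec(L[, cols, drop = FALSE], W[, cols, drop = FALSE],
                         y, ridge = ridge, maxIter = maxIter)
    p <- fit$p
    nDeg <- sum(fit$degenerate)
    if (nDeg)
      warning(nDeg, " site(s) with zero weight in a group: p set to 1")
  } else {
    p <- suppressWarnings(
      pvalueSingle(rowSums(al$mc[, i1, drop = FALSE]),
                   rowSums(al$t[, i1, drop = FALSE]),
                   rowSums(al$mc[, i2, drop = FALSE]),
                   rowSums(al$t[, i2, drop = FALSE])))
  }
  data.frame(chrom = al$chrom, pos = al$pos, m1 = m1, m2 = m2, p = p,
             stringsAsFactors = FALSE)
}

# Coverage-weighted mean replicate level per site for one group's columns.
.groupMean <- function(L, W, cols) {
  sw <- rowSums(W[, cols, drop = FALSE])
  ifelse(sw > 0, rowSums((W * L)[, cols, drop = FALSE]) / sw, 0)
}
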