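# Insert evenly spaced extra sites wherever consecutive sites inside a DMR
# interval are more than cap bp apart, so a truth region can never straddle
# the candidate-merge gap (same unambiguous-evaluation rationale as the
# inter-region spacers).
.capIntraGaps <- function(pos, regions, cap = 400) {
  dmr <- regions[regions$label == "DMR", , drop = FALSE]
  extra <- numeric(0)
  for (r in seq_len(nrow(dmr))) {
    i <- which(pos >= dmr$start[r] & pos <= dmr$end[r])
    if (length(i) < 2L) next
    g <- diff(pos[i])
    for (q in which(g > cap)) {
      k <- ceiling(g[q] / cap) - 1L
      extra <- c(extra, pos[i[q]] + round(seq_len(k) * g[q] / (k + 1L)))
    }
  }
  if (length(extra)) sort(unique(c(pos, extra))) else pos
}

# Draw site positions along [1, span] with geometric gaps (mean cfg@siteGap).
.simPositions <- function(span, siteGap) {
  prob <- 1 / siteGap
  nGuess <- as.integer(ceiling(span / siteGap * 1.3) + 100)
  pos <- cumsum(rgeom(nGuess, prob) + 1L)
  while (pos[length(pos)] < span)
    pos <- c(pos, pos[length(pos)] + cumsum(rgeom(nGuess, prob) + 1L))
  pos[pos <= span]
}

# Beta-binomial counts for one replicate over all sites. piFixed: numeric
# level or NULL; betaPar: c(a, b) or NULL; exactly one must be given.
.simCounts <- function(nSites, coverageMean, coverageDispersion,
                       piFixed = NULL, betaPar = NULL, piGiven = NULL) {
  t <- rnbinom(nSites, size = coverageDispersion, mu = coverageMean)
  pi <- if (!is.null(piGiven)) piGiven
        else if (!is.null(betaPar)) rbeta(nSites, betaPar[1], betaPar[2])
        else rep(piFixed, nSites)
  mc <- rbinom(nSites, t, pi)
  list(mc = mc, t = t)
}

# Lay out nA + nB alternating labelled regions with spacers; returns a
# data.frame(start, end, label) of drawn intervals and the genome span.
.simLayout <- function(nDmr, nNonDmr, dmrLenRange, nonDmrLenRange,
                       spacerRange) {
  nReg <- nDmr + nNonDmr
  labels <- character(nReg)
  labels[seq_len(nReg) %% 2L == 1L] <- "DMR"
  labels[seq_len(nReg) %% 2L == 0L] <- "nonDMR"
  if (nDmr != nNonDmr) {
    labels <- c(rep(c("DMR", "nonDMR"), min(nDmr, nNonDmr)),
                rep(if (nDmr > nNonDmr) "DMR" else "nonDMR",
                    abs(nDmr - nNonDmr)))
  }
  lens <- ifelse(labels == "DMR",
                 runif(nReg, dmrLenRange[1], dmrLenRange[2]),
                 runif(nReg, nonDmrLenRange[1], nonDmrLenRange[2]))
  lens <- round(lens)
  spacers <- round(runif(nReg + 1L, spacerRange[1], spacerRange[2]))
  starts <- integer(nReg); ends <- integer(nReg)
  at <- spacers[1]
  for (r in seq_len(nReg)) {
    starts[r] <- at + 1L
    ends[r] <- at + lens[r]
    at <- ends[r] + spacers[r + 1L]
  }
  list(regions = data.frame(start = starts, end = ends, label = labels,
                            stringsAsFactors = FALSE),
       span = at)
}

.mkMethylome <- function(pos, mc, t, sampleId, chrom = "chrSim") {
  Methylome(data.frame(chrom = chrom, pos = pos, strand = "+",
                       context = "CG", mc = mc, t = t),
            sampleId = sampleId, context = "CG")
}

#' Simulate a beta-binomial WGBS benchmark with ground truth
#'
#' Generates a synthetic two-group benchmark genome: labelled DMR and
#' non-DMR regions alternate along one chromosome, separated by spacers of
#' at least twice the default merge gap (so truth regions cannot fuse
#' during calling); cytosine positions follow geometric gaps; per site and
#' replicate, read coverage is negative-binomial and methylated counts are
#' binomial with a per-site beta-distributed success level (beta-binomial
#' reads). Inside DMRs group 1 levels follow \code{Beta(dmrBetaG1)} and
#' group 2 \code{Beta(dmrBetaG2)}; outside, class 1 uses a fixed background
#' level in both groups while class 2 varies the background level along the
#' genome (and, in the default dispersed mode, across replicates) according
#' to \code{class2Mode}.
#'
#' Truth-region coordinates are the span of the cytosines each drawn
#' interval contains (a region that catches no site is dropped).
#' Deterministic given \code{seed}.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @param seed Integer seed.
#' @return A list: \code{group1}, \code{group2} (lists of
#'   \linkS4class{Methylome} replicates), \code{truth} (sorted
#'   \code{GRanges} with \code{label}, \code{nSites} and \code{trueDiff}),
#'   and \code{cfg}.
#' @export
simulateBenchmark <- function(cfg = SimConfig(), seed = 1L) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(as.integer(seed))
  lay <- .simLayout(cfg@nDmr, cfg@nNonDmr, cfg@dmrLenRange,
                    cfg@nonDmrLenRange, cfg@spacerRange)
  if (lay$span > 2^31 - 1) stop("simulated layout exceeds genome span limit")
  pos <- .capIntraGaps(.simPositions(lay$span, cfg@siteGap), lay$regions)
  n <- length(pos)
  regIdx <- findInterval(pos, lay$regions$start)
  inReg <- regIdx >= 1L & pos <= lay$regions$end[pmax(regIdx, 1L)]
  regIdx[!inReg] <- 0L
  inDmr <- inReg & lay$regions$label[pmax(regIdx, 1L)] == "DMR"

  basePi <- NULL
  if (cfg@simClass == 2L && cfg@class2Mode != "independent")
    basePi <- rbeta(n, cfg@class2BackgroundBeta[1],
                    cfg@class2BackgroundBeta[2])
  simGroup <- function(glab, betaPar) {
    lapply(seq_len(cfg@repsPerGroup), function(r) {
      pi <- numeric(n)
      pi[inDmr] <- rbeta(sum(inDmr), betaPar[1], betaPar[2])
      nBg <- sum(!inDmr)
      if (cfg@simClass == 1L) {
        pi[!inDmr] <- cfg@class1Background
      } else if (cfg@class2Mode == "independent") {
        pi[!inDmr] <- rbeta(nBg, cfg@class2BackgroundBeta[1],
                            cfg@class2BackgroundBeta[2])
      } else if (cfg@class2Mode == "shared") {
        pi[!inDmr] <- basePi[!inDmr]
      } else {  # dispersed: shared base, replicate-level beta dispersion
        mu <- pmin(pmax(basePi[!inDmr], 0.02), 0.98)
        pi[!inDmr] <- rbeta(nBg, cfg@class2Dispersion * mu,
                            cfg@class2Dispersion * (1 - mu))
      }
      cnt <- .simCounts(n, cfg@coverageMean, cfg@coverageDispersion,
                        piGiven = pi)
      .mkMethylome(pos, cnt$mc, cnt$t, sprintf("%s_rep%d", glab, r))
    })
  }
  group1 <- simGroup("g1", cfg@dmrBetaG1)
  group2 <- simGroup("g2", cfg@dmrBetaG2)

  nSitesReg <- tabulate(regIdx[regIdx > 0L], nbins = nrow(lay$regions))
  keep <- which(nSitesReg > 0L)
  firstPos <- vapply(keep, function(r) pos[match(r, regIdx)], numeric(1))
  lastPos <- vapply(keep, function(r) {
    i <- which(regIdx == r); pos[i[length(i)]]
  }, numeric(1))
  truth <- GRanges("chrSim", IRanges(firstPos, lastPos))
  mcols(truth)$label <- lay$regions$label[keep]
  mcols(truth)$nSites <- nSitesReg[keep]
  muDiff <- abs(cfg@dmrBetaG1[1] / sum(cfg@dmrBetaG1) -
                  cfg@dmrBetaG2[1] / sum(cfg@dmrBetaG2))
  mcols(truth)$trueDiff <- ifelse(mcols(truth)$label == "DMR", muDiff, 0)
  list(group1 = group1, group2 = group2,
       truth = BiocGenerics::sort(truth), cfg = cfg)
}

#' Simulate a labelled training genome
#'
#' Emulates training-region derivation from orthogonal data (differential
#' chromatin-accessibility peaks or differentially expressed genes) on a
#' purely synthetic genome: candidate regions with graded effect sizes are
#' generated — strong (benchmark-style beta levels), null (background in
#' both groups), and intermediate fixed-shift regions — the realised mean
#' absolute methylation difference of each candidate is measured from the
#' simulated counts, and [selectTrainingRegions()] is applied so the
#' emitted labels satisfy the context-specific thresholds exactly.
#'
#' @param cfg A \linkS4class{SimConfig}; \code{nDmr}/\code{nNonDmr} set the
#'   numbers of strong and null candidates (a further ~20% intermediate
#'   candidates exercise the filters).
#' @param seed Integer seed.
#' @param context "CG" or "CH" (selection thresholds).
#' @return A list: \code{group1}, \code{group2}, \code{regions} (labelled
#'   \code{GRanges} passing the filters), \code{candidates} (all candidates
#'   with realised \code{meanAbsDiff}), and \code{cfg}.
#' @export
simulateTrainingRegions <- function(cfg = SimConfig(), seed = 1L,
                                    context = c("CG", "CH")) {
  context <- match.arg(context)
  stopifnot(is(cfg, "SimConfig"))
  set.seed(as.integer(seed))
  nStrong <- cfg@nDmr; nNull <- cfg@nNonDmr
  nInter <- max(2L, as.integer(round(0.3 * (nStrong + nNull))))
  lay <- .simLayout(nStrong + nInter %/% 2L, nNull + (nInter + 1L) %/% 2L,
                    cfg@dmrLenRange, cfg@nonDmrLenRange, cfg@spacerRange)
  nReg <- nrow(lay$regions)
  type <- ifelse(lay$regions$label == "DMR", "strong", "null")
  type[sample(nReg, nInter)] <- "inter"
  # graded effect sizes spanning both selection thresholds, so the labelled
  # set contains hard examples on each side of the DMR/non-DMR boundary
  interShift <- runif(nReg, 0.02, 0.35)  # used only where type == "inter"
  interBase <- runif(nReg, 0.45, 0.75)
  # real methylomes carry between-replicate biological variation; emulate
  # it with a per-region beta concentration drawn from a tight/moderate/
  # loose mix, so the classifier sees non-differential regions whose
  # replicate spread ranges from binomial-only up to Beta(2,2)-like
  regConc <- sample(c(50, 20, 10), nReg, replace = TRUE,
                    prob = c(0.3, 0.4, 0.3))
  regBase <- runif(nReg, 0.3, 0.85)  # null-region mean level

  pos <- .simPositions(lay$span, cfg@siteGap)
  n <- length(pos)
  regIdx <- findInterval(pos, lay$regions$start)
  inReg <- regIdx >= 1L & pos <= lay$regions$end[pmax(regIdx, 1L)]
  regIdx[!inReg] <- 0L
  siteType <- rep("bg", n)
  siteType[inReg] <- type[regIdx[inReg]]

  rbetaMean <- function(mu, conc) {
    mu <- pmin(pmax(mu, 0.02), 0.98)
    rbeta(length(mu), conc * mu, conc * (1 - mu))
  }
  simGroup <- function(gi) {
    lapply(seq_len(cfg@repsPerGroup), function(r) {
      # spacer background: moderate biological variation around the
      # class-1 background level
      pi <- rbetaMean(rep(cfg@class1Background, n), 12)
      iS <- siteType == "strong"
      bp <- if (gi == 1L) cfg@dmrBetaG1 else cfg@dmrBetaG2
      pi[iS] <- rbeta(sum(iS), bp[1], bp[2])
      iN <- which(siteType == "null")
      pi[iN] <- rbetaMean(regBase[regIdx[iN]], regConc[regIdx[iN]])
      iI <- which(siteType == "inter")
      mu <- interBase[regIdx[iI]]
      if (gi == 2L) mu <- mu - interShift[regIdx[iI]]
      pi[iI] <- rbetaMean(mu, regConc[regIdx[iI]])
      cnt <- .simCounts(n, cfg@coverageMean, cfg@coverageDispersion,
                        piGiven = pi)
      .mkMethylome(pos, cnt$mc, cnt$t, sprintf("tr_g%d_rep%d", gi, r))
    })
  }
  group1 <- simGroup(1L)
  group2 <- simGroup(2L)

  st <- siteStats(group1, group2)
  absDiff <- abs(st$m1 - st$m2)
  regDiff <- vapply(seq_len(nReg), function(r) {
    i <- regIdx == r
    if (any(i)) mean(absDiff[i]) else NA_real_
  }, numeric(1))
  keep <- !is.na(regDiff)
  candidates <- GRanges("chrSim", IRanges(lay$regions$start[keep],
                                          lay$regions$end[keep]))
  mcols(candidates)$meanAbsDiff <- regDiff[keep]
  mcols(candidates)$type <- type[keep]
  regions <- selectTrainingRegions(candidates, context)
  nPos <- sum(mcols(regions)$label == "DMR")
  nNeg <- sum(mcols(regions)$label == "nonDMR")
  if (nPos == 0L || nNeg == 0L)
    stop("training filters eliminated a class (", nPos, " DMR / ", nNeg,
         " non-DMR); widen the effect-size grid or region sizes")
  list(group1 = group1, group2 = group2, regions = regions,
       candidates = candidates, cfg = cfg)
}

#' Cross-group replicate permutations for null calibration
#'
#' Builds label-shuffled designs from a 2-group, 2-replicate experiment:
#' scheme \code{"cross1"} pairs replicate 1 of each original group against
#' replicate 2 of each; \code{"cross2"} pairs group-1 replicate 1 with
#' group-2 replicate 2 against the remaining two. Both mix the original
#' groups within each new treatment group, so calls on the permuted design
#' estimate the false-positive behaviour of the pipeline.
#' \code{"identity"} returns the input.
#'
#' @param groups A list of two groups, each a list of two
#'   \linkS4class{Methylome} replicates.
#' @param scheme "identity", "cross1" or "cross2".
#' @return A list of two groups (lists of methylomes).
#' @export
shuffleLabels <- function(groups, scheme = c("cross1", "cross2",
                                             "identity")) {
  scheme <- match.arg(scheme)
  if (length(groups) != 2L)
    stop("label shuffling is defined for two treatment groups")
  g1 <- groups[[1]]; g2 <- groups[[2]]
  if (scheme == "identity") return(groups)
  if (length(g1) < 2L || length(g2) < 2L)
    stop("cross schemes need >= 2 replicates per group")
  if (length(g1) != 2L || length(g2) != 2L)
    stop("cross schemes are defined for the 2x2 design")
  if (scheme == "cross1")
    list(list(g1[[1]], g2[[1]]), list(g1[[2]], g2[[2]]))
  else
    list(list(g1[[1]], g2[[2]]), list(g1[[2]], g2[[1]]))
}
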