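#' Group scored cytosines into preliminary candidate regions
#'
#' A candidate is a site with score above \code{scoreCutoff}; consecutive
#' candidates closer than \code{maxGap} bp merge into one preliminary
#' region spanning the first to last candidate. Non-candidate sites that
#' fall inside the span are retained as members — boundary refinement and
#' region summaries operate on all sites in the span.
#'
#' @param pos Sorted site positions of one chromosome (bp).
#' @param score Calibrated per-site scores aligned with \code{pos}.
#' @param params A \linkS4class{CallParams}.
#' @return A data.frame with columns \code{first}, \code{last}: site-index
#'   bounds of each preliminary region (zero rows if no candidates).
#' @export
groupCandidates <- function(pos, score, params = CallParams()) {
  stopifnot(length(pos) == length(score))
  cand <- which(score > params@scoreCutoff)
  if (!length(cand))
    return(data.frame(first = integer(), last = integer()))
  newRegion <- c(TRUE, diff(pos[cand]) >= params@maxGap)
  grp <- cumsum(newRegion)
  first <- cand[!duplicated(grp)]
  last <- cand[!duplicated(grp, fromLast = TRUE)]
  data.frame(first = first, last = last)
}

#' Refine the boundaries of a preliminary region
#'
#' Trims from each side until \code{k} consecutive member cytosines have
#' bin value \code{b >= bThreshold}: the refined start is the first site
#' beginning such a run, the refined end the last site ending one. A region
#' with no qualifying run is discarded.
#'
#' @param b Bin values (pre-smoothing) of the region's member sites, in
#'   positional order.
#' @param params A \linkS4class{CallParams} (\code{k}, \code{bThreshold}).
#' @return Integer vector \code{c(first, last)} of member indices retained,
#'   or \code{NULL} if the region is discarded.
#' @export
refineBoundaries <- function(b, params = CallParams()) {
  n <- length(b)
  k <- params@k
  if (n < k) return(NULL)
  ok <- b >= params@bThreshold
  cs <- cumsum(c(0L, ok))
  starts <- seq_len(n - k + 1L)
  full <- (cs[starts + k] - cs[starts]) == k
  if (!any(full)) return(NULL)
  left <- min(starts[full])
  right <- max(starts[full]) + k - 1L
  c(left, right)
}

# Assemble refined regions on one chromosome track. Returns a list of
# integer index ranges (global into the track) after refinement.
.assembleChromosome <- function(pos, score, b, params) {
  prelim <- groupCandidates(pos, score, params)
  out <- vector("list", nrow(prelim))
  nOut <- 0L
  for (r in seq_len(nrow(prelim))) {
    i <- prelim$first[r]; j <- prelim$last[r]
    ref <- refineBoundaries(b[i:j], params)
    if (is.null(ref)) next
    nOut <- nOut + 1L
    out[[nOut]] <- c(i + ref[1] - 1L, i + ref[2] - 1L)
  }
  out[seq_len(nOut)]
}

.applyPostFilters <- function(gr, params) {
  keep <- rep(TRUE, length(gr))
  if (!is.na(params@minSites))
    keep <- keep & mcols(gr)$nSites > params@minSites
  if (!is.na(params@minDelta))
    keep <- keep & abs(mcols(gr)$delta) > params@minDelta
  gr[keep]
}

.prepareGroup <- function(g, context) {
  if (is(g, "Methylome")) g <- list(g)
  stopifnot(length(g) >= 1L, all(vapply(g, is, TRUE, "Methylome")))
  if (context == "CG") lapply(g, combineCGStrands) else g
}

.checkModelContext <- function(model, methylomes) {
  ctx <- unique(vapply(methylomes, methContext, ""))
  if (length(ctx) != 1L)
    stop("all samples must share one context, got: ",
         paste(ctx, collapse = ", "))
  ok <- if (model@context == "CG") ctx == "CG"
        else ctx %in% c("CH", "CHG", "CHH")
  if (!ok)
    stop("model context ", model@context, " does not match data context ",
         ctx)
  ctx
}

#' Call DMRs between two treatment groups
#'
#' The full pairwise pipeline: CG strand combination, per-site differential
#' statistics ([siteStats()]), histogram features ([computeFeatures()] with
#' the model's hyperparameters), calibrated scores ([predictScores()]),
#' candidate grouping, boundary refinement, region summaries and optional
#' post-filters. Deterministic given its inputs.
#'
#' @param group1,group2 A \linkS4class{Methylome} or list of replicate
#'   methylomes per treatment group.
#' @param model A \linkS4class{TrainedModel} whose context matches the data.
#' @param params A \linkS4class{CallParams}.
#' @param weightScale Depth scale for [coverageWeight()].
#' @return A sorted \code{GRanges} of DMRs (1-based inclusive coordinates
#'   spanning the first to last member cytosine) with metadata columns
#'   \code{nSites}, \code{meanM1}, \code{meanM2}, \code{delta} (signed
#'   regional mean difference \code{mean(m1) - mean(m2)}),
#'   \code{meanAbsDiff} (mean per-site absolute difference),
#'   \code{meanScore}, \code{direction} ("hyper"/"hypo" with respect to
#'   group 1; exact ties are labelled hyper and flagged in \code{tie}).
#' @export
callPairwise <- function(group1, group2, model, params = CallParams(),
                         weightScale = 10) {
  stopifnot(is(model, "TrainedModel"), is(params, "CallParams"))
  if (is(group1, "Methylome")) group1 <- list(group1)
  if (is(group2, "Methylome")) group2 <- list(group2)
  .checkModelContext(model, c(group1, group2))
  group1 <- .prepareGroup(group1, model@context)
  group2 <- .prepareGroup(group2, model@context)
  st <- siteStats(group1, group2, weightScale = weightScale)
  cf <- computeFeatures(st, model@params)
  score <- predictScores(model, cf$features)
  stats <- cf$stats
  res <- list()
  for (ch in unique(stats$chrom)) {
    i <- which(stats$chrom == ch)
    regs <- .assembleChromosome(stats$pos[i], score[i], stats$b[i], params)
    for (rg in regs) {
      m <- i[rg[1]:rg[2]]
      d <- mean(stats$m1[m]) - mean(stats$m2[m])
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = stats$pos[m[1]],
        end = stats$pos[m[length(m)]], nSites = length(m),
        meanM1 = mean(stats$m1[m]), meanM2 = mean(stats$m2[m]),
        delta = d,
        meanAbsDiff = mean(abs(stats$m1[m] - stats$m2[m])),
        meanScore = mean(score[m]),
        direction = if (d >= 0) "hyper" else "hypo",
        tie = d == 0, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(nSites = integer(),
      meanM1 = numeric(), meanM2 = numeric(), delta = numeric(),
      meanAbsDiff = numeric(), meanScore = numeric(),
      direction = character(), tie = logical())
    return(gr)
  }
  df <- do.call(rbind, res)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr) <- S4Vectors::DataFrame(df[, !(names(df) %in%
                                             c("chrom", "start", "end")),
                                       drop = FALSE])
  .applyPostFilters(BiocGenerics::sort(gr), params)
}

#' Call DMRs across three or more groups (time series / multi-group)
#'
#' Scores every cytosine under each of the \code{choose(n, 2)} pairwise
#' group comparisons (on a common site set, the union across all samples),
#' sums the calibrated pair scores into a final per-cytosine score, and
#' groups candidates with the score cutoff scaled by the number of pairs
#' (preserving the per-pair meaning of the default 0.1). Boundary
#' refinement uses, at each site, the maximum bin value over all pairs.
#' The output carries the mean methylation level per group and, for every
#' group pair, the mean level difference and its direction.
#'
#' @param groups A named (or unnamed) list of n >= 3 groups, each a
#'   \linkS4class{Methylome} or list of replicates.
#' @param model A \linkS4class{TrainedModel}.
#' @param params A \linkS4class{CallParams}; \code{scoreCutoff} is
#'   interpreted per pair.
#' @param weightScale Depth scale for [coverageWeight()].
#' @return A sorted \code{GRanges} with columns \code{nSites},
#'   \code{meanScore} (mean summed score), \code{meanAbsDiff} (max over
#'   pairs of the mean absolute difference), \code{meanM_<group>} and
#'   per-pair \code{diff_<g1>_<g2>} / \code{dir_<g1>_<g2>}.
#' @export
callTimeseries <- function(groups, model, params = CallParams(),
                           weightScale = 10) {
  stopifnot(is(model, "TrainedModel"))
  n <- length(groups)
  if (n < 3L)
    stop("time-series mode needs >= 3 groups; use callPairwise for 2")
  groups <- lapply(groups, function(g) if (is(g, "Methylome")) list(g)
                   else g)
  .checkModelContext(model, unlist(groups))
  groups <- lapply(groups, .prepareGroup, context = model@context)
  gnames <- names(groups)
  if (is.null(gnames)) gnames <- paste0("g", seq_len(n))
  sizes <- lengths(groups)
  al <- .alignCounts(unlist(groups))
  colIdx <- split(seq_len(sum(sizes)), rep(seq_len(n), sizes))
  L <- ifelse(al$t > 0, al$mc / al$t, 0)
  W <- coverageWeight(al$t, scale = weightScale)
  mg <- vapply(colIdx, function(cols) .groupMean(L, W, cols),
               numeric(length(al$pos)))
  pairs <- utils::combn(n, 2)
  nPairs <- ncol(pairs)
  scoreSum <- numeric(length(al$pos))
  bMax <- numeric(length(al$pos))
  pairDiff <- matrix(0, length(al$pos), nPairs)
  for (q in seq_len(nPairs)) {
    i <- pairs[1, q]; j <- pairs[2, q]
    st <- .statsFromAligned(al, colIdx[[i]], colIdx[[j]],
                            weightScale = weightScale)
    cf <- computeFeatures(st, model@params)
    scoreSum <- scoreSum + predictScores(model, cf$features)
    bMax <- pmax(bMax, cf$stats$b)
    pairDiff[, q] <- st$m1 - st$m2
  }
  tsParams <- params
  tsParams@scoreCutoff <- params@scoreCutoff * nPairs
  res <- list()
  for (ch in unique(al$chrom)) {
    i <- which(al$chrom == ch)
    regs <- .assembleChromosome(al$pos[i], scoreSum[i], bMax[i], tsParams)
    for (rg in regs) {
      m <- i[rg[1]:rg[2]]
      row <- data.frame(chrom = ch, start = al$pos[m[1]],
                        end = al$pos[m[length(m)]], nSites = length(m),
                        meanScore = mean(scoreSum[m]),
                        stringsAsFactors = FALSE)
      for (g in seq_len(n))
        row[[paste0("meanM_", gnames[g])]] <- mean(mg[m, g])
      pairAbs <- numeric(nPairs); pairDelta <- numeric(nPairs)
      for (q in seq_len(nPairs)) {
        d <- mean(pairDiff[m, q])
        pairAbs[q] <- mean(abs(pairDiff[m, q]))
        pairDelta[q] <- d
        lab <- paste0(gnames[pairs[1, q]], "_", gnames[pairs[2, q]])
        row[[paste0("diff_", lab)]] <- d
        row[[paste0("dir_", lab)]] <- if (d >= 0) "hyper" else "hypo"
      }
      row$meanAbsDiff <- max(pairAbs)
      row$delta <- pairDelta[which.max(abs(pairDelta))]
      res[[length(res) + 1L]] <- row
    }
  }
  if (!length(res)) return(GRanges())
  df <- do.call(rbind, res)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr) <- S4Vectors::DataFrame(df[, !(names(df) %in%
                                             c("chrom", "start", "end")),
                                       drop = FALSE])
  .applyPostFilters(BiocGenerics::sort(gr), params)
}
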