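#' Bin value: p-value-boosted methylation difference
#'
#' \code{b = |m1 - m2| * exp(1 - p)}. The exponential term lets small
#' (significant) p-values amplify the difference by up to a factor of
#' \code{e}, while \code{p = 1} leaves the raw difference; range [0, e].
#'
#' @param m1,m2 Group methylation levels in [0, 1] (vectorised).
#' @param p P-values in [0, 1].
#' @return Bin values \code{b >= 0}.
#' @export
binValue <- function(m1, m2, p) {
  if (any(m1 < 0 | m1 > 1 | m2 < 0 | m2 > 1))
    stop("methylation levels must be in [0, 1]")
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  abs(m1 - m2) * exp(1 - p)
}

#' Moving-average smoothing of a per-chromosome track
#'
#' Centred moving average over \code{span} cytosines (index-based, not
#' bp-based). At chromosome ends the window shrinks symmetrically, so the
#' first and last values of a span-3 smooth are unchanged.
#'
#' @param x Ordered per-chromosome track values.
#' @param span Odd window size in cytosines (default 3).
#' @return Smoothed track, same length as \code{x}.
#' @export
smoothTrack <- function(x, span = 3L) {
  span <- as.integer(span)
  if (span < 1L || span %% 2L == 0L) stop("span must be odd and >= 1")
  n <- length(x)
  if (n == 0L || span == 1L) return(as.numeric(x))
  h <- (span - 1L) %/% 2L
  idx <- seq_len(n)
  hw <- pmin(h, idx - 1L, n - idx)  # symmetric shrink at ends
  cs <- cumsum(c(0, x))
  (cs[idx + hw + 1L] - cs[idx - hw]) / (2L * hw + 1L)
}

#' Min-max scale a per-chromosome track to [0, 1]
#'
#' \code{(x - min) / (max - min)} elementwise; a constant track maps to
#' all zeros.
#'
#' @param x Per-chromosome track values.
#' @return Scaled track in [0, 1].
#' @export
scaleTrack <- function(x) {
  if (!length(x)) return(numeric())
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Distance vote weight
#'
#' Linear taper of a neighbour's histogram contribution with distance from
#' the window-centre cytosine: \code{v = 1 - |l - lc| / d} when
#' \code{|l - lc| < d}, else 0.
#'
#' @param l Neighbour position(s), bp.
#' @param lc Centre position, bp.
#' @param d Maximum allowed distance, bp (> 0).
#' @return Vote weights in [0, 1].
#' @export
voteWeight <- function(l, lc, d) {
  if (any(d <= 0)) stop("d must be > 0")
  dist <- abs(l - lc)
  ifelse(dist < d, 1 - dist / d, 0)
}

.binIndex <- function(bs, bins) pmin(floor(bs * bins), bins - 1L)

#' Histogram feature for one cytosine
#'
#' Tallies distance-weighted votes from the sites of a window into
#' \code{bins} histogram bins: each site's scaled bin value \code{bs}
#' selects the bin (\code{min(floor(bs * bins), bins - 1)}, so
#' \code{bs = 1} lands in the top bin) and its [voteWeight()] relative to
#' the centre site is the contribution. The tally is normalised to sum to
#' one; if no site is within voting distance an all-zero sentinel row is
#' returned.
#'
#' @param pos Window site positions (bp).
#' @param bs Window scaled bin values in [0, 1].
#' @param centerIndex Index of the featurized cytosine within the window.
#' @param params A \linkS4class{FeatureParams}.
#' @return Numeric vector of length \code{params@bins}.
#' @export
histogramFeature <- function(pos, bs, centerIndex, params = FeatureParams()) {
  stopifnot(length(pos) == length(bs), centerIndex >= 1,
            centerIndex <= length(pos))
  v <- voteWeight(pos, pos[centerIndex], params@d)
  bin <- .binIndex(bs, params@bins)
  out <- numeric(params@bins)
  for (i in seq_along(pos)) out[bin[i] + 1L] <- out[bin[i] + 1L] + v[i]
  s <- sum(out)
  if (s > 0) out / s else out
}

#' Histogram features for every cytosine of a chromosome
#'
#' Slides a window of \code{params@w} cytosines (truncated at chromosome
#' ends) across a sorted single-chromosome track and computes the
#' [histogramFeature()] of every site. Equivalent to calling
#' \code{histogramFeature} per site, but vectorised over window offsets.
#'
#' @param pos Sorted site positions (bp) of one chromosome.
#' @param bs Scaled bin values aligned with \code{pos}.
#' @param params A \linkS4class{FeatureParams}.
#' @return A numeric matrix with \code{length(pos)} rows and
#'   \code{params@bins} columns; every row sums to 1 or is all zero.
#' @export
featurizeChromosome <- function(pos, bs, params = FeatureParams()) {
  n <- length(pos)
  stopifnot(length(bs) == n)
  bins <- params@bins
  M <- matrix(0, n, bins)
  if (n == 0L) return(M)
  h <- (params@w - 1L) %/% 2L
  bin <- .binIndex(bs, bins) + 1L
  idx <- seq_len(n)
  for (off in (-h):h) {
    j <- idx + off
    keep <- j >= 1L & j <= n
    i <- idx[keep]; j <- j[keep]
    v <- 1 - abs(pos[j] - pos[i]) / params@d
    pos_ok <- v > 0
    i <- i[pos_ok]; j <- j[pos_ok]; v <- v[pos_ok]
    if (!length(i)) next
    cb <- cbind(i, bin[j])
    M[cb] <- M[cb] + v
  }
  s <- rowSums(M)
  nz <- s > 0
  M[nz, ] <- M[nz, , drop = FALSE] / s[nz]
  M
}

#' Full per-site feature computation across chromosomes
#'
#' Applies the whole per-site transform to the output of [siteStats()]:
#' bin values (\code{b}), per-chromosome moving-average smoothing and
#' min-max scaling (\code{bs}), and windowed histogram features.
#'
#' @param stats Data frame from [siteStats()] (\code{chrom, pos, m1, m2,
#'   p}), sorted by (chrom, pos).
#' @param params A \linkS4class{FeatureParams}.
#' @return A list with \code{stats} (input plus \code{b} and \code{bs}
#'   columns) and \code{features} (matrix, one row per site).
#' @export
computeFeatures <- function(stats, params = FeatureParams()) {
  b <- binValue(stats$m1, stats$m2, stats$p)
  bs <- numeric(nrow(stats))
  feat <- matrix(0, nrow(stats), params@bins)
  for (ch in unique(stats$chrom)) {
    i <- which(stats$chrom == ch)
    bsi <- scaleTrack(smoothTrack(b[i], params@smoothSpan))
    bs[i] <- bsi
    feat[i, ] <- featurizeChromosome(stats$pos[i], bsi, params)
  }
  stats$b <- b
  stats$bs <- bs
  list(stats = stats, features = feat)
}
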