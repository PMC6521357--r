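test_that("candidate grouping follows score cutoff and gap rules", {
  p <- CallParams()
  g <- groupCandidates(c(100, 200), c(0.5, 0.5), p)
  expect_equal(nrow(g), 1L)
  expect_equal(unlist(g[1, ]), c(first = 1L, last = 2L))
  g <- groupCandidates(c(100, 700), c(0.5, 0.5), p)
  expect_equal(nrow(g), 2L)
  expect_equal(nrow(groupCandidates(c(100, 700), c(0.1, 0.05), p)), 0L)
  # non-candidate members inside the span are retained
  g <- groupCandidates(c(100, 150, 200), c(0.5, 0.01, 0.5), p)
  expect_equal(unlist(g[1, ]), c(first = 1L, last = 3L))
  # exactly maxGap does not merge (rule is strictly less than)
  g <- groupCandidates(c(100, 600), c(0.5, 0.5), p)
  expect_equal(nrow(g), 2L)
})

bruteRefine <- function(b, k, th) {
  n <- length(b)
  ok <- b >= th
  starts <- which(vapply(seq_len(max(n - k + 1, 0)),
                         function(i) all(ok[i:(i + k - 1)]), TRUE))
  if (!length(starts)) return(NULL)
  c(min(starts), max(starts) + k - 1L)
}

test_that("boundary refinement trims to the outermost qualifying runs", {
  p <- CallParams()
  expect_equal(refineBoundaries(c(0.05, 0.2, 0.2, 0.2, 0.05), p),
               c(2L, 5L) - c(0L, 1L))  # sites 2..4
  expect_equal(refineBoundaries(rep(0.3, 6), p), c(1L, 6L))
  expect_null(refineBoundaries(c(0.2, 0.05, 0.2, 0.05), p))
  expect_null(refineBoundaries(c(0.5, 0.5), p))  # fewer members than k
  set.seed(61)
  for (i in 1:100) {
    b <- runif(sample(1:20, 1), 0, 0.3)
    k <- sample(1:4, 1)
    pp <- CallParams(k = k)
    expect_equal(refineBoundaries(b, pp), bruteRefine(b, k, 0.1))
  }
})

test_that("refinement never widens and is monotone in its threshold", {
  set.seed(63)
  for (i in 1:50) {
    b <- runif(sample(3:25, 1), 0, 0.4)
    r1 <- refineBoundaries(b, CallParams(bThreshold = 0.1))
    r2 <- refineBoundaries(b, CallParams(bThreshold = 0.2))
    if (!is.null(r1)) {
      expect_gte(r1[1], 1L)
      expect_lte(r1[2], length(b))
    }
    if (!is.null(r2)) {
      expect_false(is.null(r1))  # survival is monotone in threshold
      expect_gte(r2[1], r1[1])   # higher threshold trims at least as much
      expect_lte(r2[2], r1[2])
    }
  }
})

test_that("merging is gap-monotone", {
  set.seed(65)
  for (i in 1:20) {
    n <- 60
    pos <- cumsum(sample(50:400, n, TRUE))
    score <- runif(n, 0, 0.4)
    n1 <- nrow(groupCandidates(pos, score, CallParams(maxGap = 300)))
    n2 <- nrow(groupCandidates(pos, score, CallParams(maxGap = 600)))
    expect_lte(n2, n1)
  }
})

test_that("identical methylomes yield no DMRs and calls are deterministic", {
  m <- toyMethylome(pos = cumsum(rep(100L, 40)),
                    mc = rep(c(2L, 7L), 20), t = rep(10L, 40))
  model <- smallModel()
  params <- CallParams(minSites = 5, minDelta = 0.2)
  out <- callPairwise(list(m, m, m), list(m, m, m), model, params)
  expect_length(out, 0L)
  sim <- simulateBenchmark(SimConfig(nDmr = 10L, nNonDmr = 10L), seed = 67)
  d1 <- callPairwise(sim$group1, sim$group2, model, params)
  d2 <- callPairwise(sim$group1, sim$group2, model, params)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_gt(length(d1), 0L)
  # intervals are sorted and non-overlapping
  expect_true(all(diff(BiocGenerics::start(d1)) > 0))
  expect_true(all(BiocGenerics::start(d1)[-1] >
                    BiocGenerics::end(d1)[-length(d1)]))
})

test_that("reported DMR boundaries satisfy the k-run refinement rule", {
  model <- smallModel()
  sim <- simulateBenchmark(SimConfig(nDmr = 15L, nNonDmr = 15L), seed = 69)
  params <- CallParams()
  dmrs <- callPairwise(sim$group1, sim$group2, model, params)
  expect_gt(length(dmrs), 0L)
  # recompute the b track the caller used
  g1 <- lapply(sim$group1, combineCGStrands)
  g2 <- lapply(sim$group2, combineCGStrands)
  st <- siteStats(g1, g2)
  b <- binValue(st$m1, st$m2, st$p)
  for (i in seq_along(dmrs)) {
    m <- which(st$pos >= BiocGenerics::start(dmrs)[i] &
                 st$pos <= BiocGenerics::end(dmrs)[i])
    expect_gte(length(m), params@k)
    expect_true(all(b[m[1:params@k]] >= params@bThreshold))
    tailIdx <- m[(length(m) - params@k + 1):length(m)]
    expect_true(all(b[tailIdx] >= params@bThreshold))
  }
})

test_that("time-series mode sums pair scores and reports per-pair metrics", {
  model <- smallModel()
  set.seed(71)
  n <- 400
  pos <- cumsum(sample(60:140, n, TRUE))
  inReg <- 150:175
  mkGroup <- function(levels) {
    lapply(1:3, function(r) {
      t <- rep(30L, n)
      toyMethylome(pos = pos, mc = rbinom(n, t, levels), t = t,
                   sampleId = paste0("s", r))
    })
  }
  # a two-step time series: region A loses methylation after time 1,
  # region B only at time 3, so every group pair carries signal somewhere
  regA <- 60:85
  base <- rep(0.7, n)
  lv1 <- base
  lv2 <- base; lv2[regA] <- 0.1
  lv3 <- lv2; lv3[inReg] <- 0.1
  g1 <- mkGroup(lv1); g2 <- mkGroup(lv2); g3 <- mkGroup(lv3)
  expect_error(callTimeseries(list(g1, g2), model), ">= 3 groups")
  outNull <- callTimeseries(list(mkGroup(base), mkGroup(base),
                                 mkGroup(base)), model,
                            CallParams(minSites = 5, minDelta = 0.2))
  expect_length(outNull, 0L)
  out <- callTimeseries(list(g1 = g1, g2 = g2, g3 = g3), model,
                        CallParams(minSites = 5, minDelta = 0.2))
  expect_gte(length(out), 2L)
  hitA <- out[which.max(pmin(BiocGenerics::end(out), pos[max(regA)]) -
                          pmax(BiocGenerics::start(out), pos[min(regA)]))]
  hitB <- out[which.max(pmin(BiocGenerics::end(out), pos[max(inReg)]) -
                          pmax(BiocGenerics::start(out), pos[min(inReg)]))]
  # region A changed at time 2: pairs (1,2) and (1,3) differ, (2,3) not
  mdA <- mcols(hitA)
  expect_gt(mdA$diff_g1_g2, 0.4)
  expect_gt(mdA$diff_g1_g3, 0.4)
  expect_lt(abs(mdA$diff_g2_g3), 0.1)
  # region B changed at time 3: pairs (1,3) and (2,3) differ, (1,2) not
  mdB <- mcols(hitB)
  expect_lt(abs(mdB$diff_g1_g2), 0.1)
  expect_gt(mdB$diff_g1_g3, 0.4)
  expect_gt(mdB$diff_g2_g3, 0.4)
  expect_equal(mdB$dir_g1_g3, "hyper")
})

test_that("per-cytosine time-series scores equal the sum of pair scores", {
  model <- smallModel()
  set.seed(73)
  n <- 40
  pos <- cumsum(sample(60:140, n, TRUE))
  groups <- lapply(1:3, function(g) {
    lapply(1:2, function(r) {
      t <- rep(10L, n)
      toyMethylome(pos = pos, mc = rbinom(n, t, runif(n)), t = t)
    })
  })
  # manual pair-score sum on the common site set
  pairScore <- function(a, b) {
    st <- siteStats(lapply(a, combineCGStrands),
                    lapply(b, combineCGStrands))
    predictScores(model, computeFeatures(st, featureParams(model))$features)
  }
  total <- pairScore(groups[[1]], groups[[2]]) +
    pairScore(groups[[1]], groups[[3]]) +
    pairScore(groups[[2]], groups[[3]])
  # regions found by timeseries with cutoff c correspond to summed score
  # > 3 * c; verify against the manual sum via a high-resolution call
  out <- callTimeseries(groups, model,
                        CallParams(scoreCutoff = max(total) / 3 + 1e-9))
  expect_length(out, 0L)  # cutoff above the max summed score: nothing
  outAll <- callTimeseries(groups, model, CallParams(scoreCutoff = 1e-9))
  # every site is a candidate; one region spanning all sites (gaps < 500)
  expect_equal(length(outAll), 1L)
  expect_equal(mcols(outAll)$meanScore, mean(total), tolerance = 1e-9)
})

test_that("label-shuffled replicates produce almost no filtered DMRs", {
  model <- smallModel()
  cfg <- SimConfig(nDmr = 30L, nNonDmr = 30L, repsPerGroup = 2L)
  sim <- simulateBenchmark(cfg, seed = 75)
  params <- CallParams(minSites = 5, minDelta = 0.2)
  real <- callPairwise(sim$group1, sim$group2, model, params)
  shuf <- shuffleLabels(list(sim$group1, sim$group2), "cross1")
  null1 <- suppressWarnings(callPairwise(shuf[[1]], shuf[[2]], model,
                                         params))
  shuf2 <- shuffleLabels(list(sim$group1, sim$group2), "cross2")
  null2 <- suppressWarnings(callPairwise(shuf2[[1]], shuf2[[2]], model,
                                         params))
  expect_gt(length(real), 20L)
  expect_lte(length(null1), ceiling(0.05 * length(real)))
  expect_lte(length(null2), ceiling(0.05 * length(real)))
})
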