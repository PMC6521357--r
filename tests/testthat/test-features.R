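test_that("bin value follows |m1-m2| * exp(1-p)", {
  expect_equal(binValue(0.7, 0.7, 1), 0)
  expect_equal(binValue(1, 0, 1), 1)
  expect_equal(binValue(0.8, 0.3, 0.05), 0.5 * exp(0.95), tolerance = 1e-12)
  expect_error(binValue(1.2, 0, 0.5), "levels")
  expect_error(binValue(0.5, 0.5, -0.1), "p-values")
})

test_that("moving-average smoothing shrinks symmetrically at ends", {
  expect_equal(smoothTrack(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(smoothTrack(c(0, 1, 0)), c(0, 1 / 3, 0))
  expect_equal(smoothTrack(0.7), 0.7)
  expect_equal(smoothTrack(numeric()), numeric())
  expect_error(smoothTrack(1:5, span = 2), "odd")
  # independent oracle on random tracks
  set.seed(21)
  for (i in 1:20) {
    x <- runif(sample(1:30, 1))
    span <- sample(c(1L, 3L, 5L), 1)
    h <- (span - 1L) %/% 2L
    ref <- vapply(seq_along(x), function(j) {
      hw <- min(h, j - 1L, length(x) - j)
      mean(x[(j - hw):(j + hw)])
    }, 0)
    expect_equal(smoothTrack(x, span), ref, tolerance = 1e-12)
  }
})

test_that("per-chromosome scaling maps tracks to [0,1]", {
  expect_equal(scaleTrack(c(0, 0.5, 1)), c(0, 0.5, 1))
  expect_equal(scaleTrack(c(0.2, 0.2)), c(0, 0))
  expect_equal(scaleTrack(c(0.1, 0.3, 0.5)), c(0, 0.5, 1))
  expect_equal(scaleTrack(numeric()), numeric())
})

test_that("vote weight tapers linearly and cuts off at d", {
  expect_equal(voteWeight(100, 100, 250), 1)
  expect_equal(voteWeight(350, 100, 250), 0)
  expect_equal(voteWeight(200, 100, 250), 0.6)
  expect_equal(voteWeight(500, 100, 250), 0)
  expect_error(voteWeight(1, 1, 0), "d must be")
})

test_that("histogram voting matches the hand examples", {
  p <- FeatureParams("CG")
  f <- histogramFeature(c(0, 100, 200), rep(0, 3), 2L, p)
  expect_equal(f, c(1, rep(0, 9)))
  # only the centre votes: others at exactly d away
  f <- histogramFeature(c(0, 250, 500), c(0, 0.55, 0), 2L, p)
  expect_equal(f, c(rep(0, 5), 1, rep(0, 4)))
  # 5-site hand example vs brute-force tally
  pos <- c(0, 100, 200, 300, 400)
  bs <- c(0.05, 0.55, 0.95, 0.55, 0.05)
  f <- histogramFeature(pos, bs, 3L, p)
  tally <- numeric(10)
  for (i in seq_along(pos)) {
    v <- max(0, 1 - abs(pos[i] - pos[3]) / p@d)
    if (abs(pos[i] - pos[3]) >= p@d) v <- 0
    b <- min(floor(bs[i] * 10), 9) + 1
    tally[b] <- tally[b] + v
  }
  expect_equal(f, tally / sum(tally), tolerance = 1e-12)
  # bs = 1 lands in the top bin
  expect_equal(which.max(histogramFeature(c(0, 50), c(1, 1), 1L, p)), 10L)
})

naiveFeaturize <- function(pos, bs, params) {
  n <- length(pos)
  h <- (params@w - 1L) %/% 2L
  t(vapply(seq_len(n), function(i) {
    win <- max(1L, i - h):min(n, i + h)
    histogramFeature(pos[win], bs[win], which(win == i), params)
  }, numeric(params@bins)))
}

test_that("vectorised featurization equals the naive per-site computation", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(c(1, 5, 30, 80), 1)
    pos <- cumsum(sample(10:300, n, TRUE))
    bs <- runif(n)
    params <- FeatureParams("CG", w = sample(c(3L, 11L), 1))
    M <- featurizeChromosome(pos, bs, params)
    expect_equal(M, naiveFeaturize(pos, bs, params), tolerance = 1e-12)
    s <- rowSums(M)
    expect_true(all(abs(s - 1) < 1e-9 | s == 0))
  }
})

test_that("features are translation invariant and locally determined", {
  set.seed(33)
  pos <- cumsum(sample(20:200, 50, TRUE))
  bs <- runif(50)
  params <- FeatureParams("CG")
  M1 <- featurizeChromosome(pos, bs, params)
  M2 <- featurizeChromosome(pos + 77777L, bs, params)
  expect_identical(M1, M2)
})

test_that("stronger in-region differences shift histogram mass upward", {
  # monotone mass shift: raising |m1-m2| (p fixed) in a region never
  # lowers the top-bin mass of features centred in that region
  set.seed(35)
  n <- 60
  pos <- cumsum(sample(50:150, n, TRUE))
  p <- runif(n, 0.2, 1)
  m2 <- rep(0.3, n)
  inRegion <- 25:35
  mkStats <- function(diffIn) {
    m1 <- m2 + 0.05
    m1[inRegion] <- m2[inRegion] + diffIn
    data.frame(chrom = "c", pos = pos, m1 = m1, m2 = m2, p = p)
  }
  params <- FeatureParams("CG")
  low <- computeFeatures(mkStats(0.3), params)$features
  high <- computeFeatures(mkStats(0.6), params)$features
  topMass <- function(M) rowSums(M[inRegion, 6:10, drop = FALSE])
  expect_true(all(topMass(high) >= topMass(low) - 1e-9))
})

test_that("computeFeatures treats chromosomes independently", {
  st <- data.frame(chrom = rep(c("a", "b"), each = 4),
                   pos = rep(c(100, 200, 300, 400), 2),
                   m1 = c(0.9, 0.9, 0.9, 0.9, 0.3, 0.3, 0.3, 0.3),
                   m2 = c(0.1, 0.1, 0.1, 0.1, 0.3, 0.3, 0.3, 0.3),
                   p = rep(0.01, 8))
  cf <- computeFeatures(st, FeatureParams("CG"))
  # chromosome b is constant -> scaled to 0 on each chromosome separately
  expect_true(all(cf$stats$bs == 0))
  aOnly <- computeFeatures(st[st$chrom == "a", ], FeatureParams("CG"))
  expect_equal(cf$features[1:4, ], aOnly$features)
})
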