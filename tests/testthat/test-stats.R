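test_that("methylation level and coverage weight behave as defined", {
  expect_equal(methylationLevel(0, 10), 0)
  expect_equal(methylationLevel(10, 10), 1)
  expect_equal(methylationLevel(3, 12), 0.25)
  expect_equal(methylationLevel(0, 0), 0)  # zero coverage is inert
  expect_error(methylationLevel(5, 3), "exceed")

  expect_equal(coverageWeight(0), 0)
  expect_lt(coverageWeight(5), coverageWeight(20))
  expect_equal(coverageWeight(10, scale = 10), 2 / (1 + exp(-1)) - 1,
               tolerance = 1e-12)
  w <- coverageWeight(0:200)
  expect_true(all(diff(w) > 0) && all(w >= 0 & w < 1))
  expect_error(coverageWeight(5, scale = 0), "positive")
})

test_that("pooled z-test matches its closed form and prop.test", {
  expect_equal(pvalueSingle(5, 10, 5, 10), 1)
  z <- 1 / sqrt(0.25 * 0.2)
  expect_equal(pvalueSingle(10, 10, 0, 10), 2 * pnorm(-z), tolerance = 1e-12)
  expect_equal(pvalueSingle(8, 10, 2, 10), 2 * pnorm(-0.6 / sqrt(0.05)),
               tolerance = 1e-12)
  # degenerate pooled proportions
  expect_equal(pvalueSingle(0, 10, 0, 10), 1)
  expect_equal(pvalueSingle(10, 10, 10, 10), 1)
  expect_warning(p0 <- pvalueSingle(0, 0, 5, 10), "zero coverage")
  expect_equal(p0, 1)
  # independent oracle: chi-square two-proportion test without continuity
  # correction is the square of the pooled z statistic
  set.seed(5)
  for (i in 1:50) {
    t1 <- sample(3:40, 1); t2 <- sample(3:40, 1)
    mc1 <- rbinom(1, t1, 0.5); mc2 <- rbinom(1, t2, 0.5)
    p <- pvalueSingle(mc1, t1, mc2, t2)
    phat <- (mc1 + mc2) / (t1 + t2)
    if (phat > 0 && phat < 1) {
      ref <- suppressWarnings(
        prop.test(c(mc1, mc2), c(t1, t2), correct = FALSE)$p.value)
      expect_equal(p, ref, tolerance = 1e-9)
    }
  }
})

test_that("weighted logistic LRT agrees with an independent optimiser", {
  set.seed(11)
  labels <- c(0, 0, 0, 1, 1, 1)
  for (i in 1:100) {
    lv <- runif(6)
    w <- runif(6, 0.1, 1)
    p <- pvalueReplicates(lv, labels, w)
    expect_equal(p, refWlogitLRT(lv, labels, w), tolerance = 1e-6)
  }
})

test_that("replicate LRT handles nulls, separation and symmetries", {
  labels <- c(0, 0, 0, 1, 1, 1)
  lv <- c(0.4, 0.5, 0.6, 0.4, 0.5, 0.6)
  expect_gt(pvalueReplicates(lv, labels, rep(1, 6)), 0.99)
  # perfect separation stays finite and significant under the ridge
  sep <- pvalueReplicates(c(0.9, 0.92, 0.88, 0.1, 0.12, 0.08), labels,
                          rep(1, 6))
  expect_true(is.finite(sep) && sep <= 0.05 && sep >= 1e-300)
  expect_equal(sep, refWlogitLRT(c(0.9, 0.92, 0.88, 0.1, 0.12, 0.08),
                                 labels, rep(1, 6)), tolerance = 1e-6)
  # label-swap and replicate-reorder invariance
  set.seed(3)
  lv <- runif(6); w <- runif(6, 0.2, 1)
  p1 <- pvalueReplicates(lv, labels, w)
  expect_equal(p1, pvalueReplicates(lv, 1 - labels, w), tolerance = 1e-9)
  o <- c(3, 1, 2, 6, 4, 5)
  expect_equal(p1, pvalueReplicates(lv[o], labels[o], w[o]),
               tolerance = 1e-9)
  # degenerate weights
  expect_warning(pz <- pvalueReplicates(lv, labels, c(1, 1, 1, 0, 0, 0)),
                 "zero total weight")
  expect_equal(pz, 1)
  expect_error(pvalueReplicates(runif(3), c(0, 0, 1)), ">= 2 observations")
})

test_that("null z-test rejection rates are near-nominal", {
  # the pooled z-test is discrete in (mc1, mc2), so its null CDF is a step
  # function around the uniform; check simulated rates against the exact
  # enumerated null, and the exact rates against nominal levels
  t <- 50L
  counts <- expand.grid(mc1 = 0:t, mc2 = 0:t)
  prob <- dbinom(counts$mc1, t, 0.5) * dbinom(counts$mc2, t, 0.5)
  pAll <- pvalueSingle(counts$mc1, t, counts$mc2, t)
  exactRate <- function(a) sum(prob[pAll <= a])
  set.seed(17)
  n <- 10000
  p <- pvalueSingle(rbinom(n, t, 0.5), t, rbinom(n, t, 0.5), t)
  for (a in c(0.01, 0.05, 0.25)) {
    ex <- exactRate(a)
    emp <- mean(p <= a)
    expect_lt(abs(emp - ex), 3.3 * sqrt(ex * (1 - ex) / n) + 1e-12)
    expect_lt(ex, a * 1.2 + 0.01)  # calibrated up to discreteness
  }
})

test_that("siteStats aligns union sites and falls back without replicates", {
  g1 <- list(toyMethylome(pos = c(100L, 200L), mc = c(9L, 1L),
                          t = c(10L, 10L)),
             toyMethylome(pos = c(100L, 300L), mc = c(8L, 5L),
                          t = c(10L, 10L), sampleId = "b"))
  g2 <- list(toyMethylome(pos = c(100L, 200L), mc = c(1L, 2L),
                          t = c(10L, 10L)),
             toyMethylome(pos = c(100L, 200L), mc = c(2L, 1L),
                          t = c(10L, 10L), sampleId = "d"))
  st <- suppressWarnings(siteStats(g1, g2))
  expect_equal(st$pos, c(100L, 200L, 300L))      # union of sites
  expect_equal(st$m1[1], 0.85)                   # equal weights at t = 10
  expect_true(all(st$p >= 0 & st$p <= 1))
  # single replicate per group: pooled z-test on summed counts
  st1 <- siteStats(g1[[1]], g2[[1]])
  expect_equal(st1$p, pvalueSingle(c(9, 1), c(10, 10), c(1, 2), c(10, 10)),
               tolerance = 1e-12)
})
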