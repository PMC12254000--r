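test_that("profiles aggregate voxels by layer with depth ordering", {
  lab <- rep(1:4, each = 10)
  prof <- buildProfile(rep(2, 40), lab)
  expect_equal(prof@mean, rep(2, 4))
  expect_equal(prof@se, rep(0, 4))
  expect_equal(prof@depth, (1:4 - 0.5) / 4)
  expect_error(buildProfile(rnorm(10), rep(1, 10)), ">= 2 layers")
  expect_error(buildProfile(rnorm(10), rep(c(1, 3), 5)), "gaps")
})

test_that("two-peak scenario profiles peak at the generator's depths", {
  run <- simulateTaskRun(makePhysiology(15, "task_two_peak"),
                         noiseSd = noiseless, seed = 1, voxelsPerLayer = 3)
  q <- quantifyRun(run, dropTransition = 0)
  prof <- laminarProfile(q$depth, q$cbfPercent)
  y <- prof@mean
  tr <- groundTruth(run)
  peaks <- which(vapply(2:14, function(i) y[i] > y[i - 1] && y[i] > y[i + 1],
                        logical(1))) + 1L
  truthPeaks <- which(vapply(2:14, function(i)
    tr@cbfResponse[i] > tr@cbfResponse[i - 1] &&
      tr@cbfResponse[i] > tr@cbfResponse[i + 1], logical(1))) + 1L
  expect_identical(peaks, truthPeaks)
})

test_that("Gaussian model fits: exact curves and the adjusted-R2 formula", {
  d <- layerDepths(15)
  y1 <- 2 + 1.3 * exp(-(d - d[8])^2 / (2 * 0.15^2))
  f1 <- gaussianModelFit(laminarProfile(d, y1), 1)
  expect_equal(f1$r2, 1, tolerance = 1e-8)
  expect_identical(f1$nParams, 4L)

  # adjusted R2: R2 = 0.9, n = 15, p = 4 -> 0.86
  expect_equal(1 - (1 - 0.9) * (15 - 1) / (15 - 4 - 1), 0.86)

  y2 <- 1 + exp(-(d - 0.25)^2 / (2 * 0.08^2)) +
    0.8 * exp(-(d - 0.75)^2 / (2 * 0.08^2))
  prof2 <- laminarProfile(d, y2)
  f2 <- gaussianModelFit(prof2, 2)
  f2s <- gaussianModelFit(prof2, 1)
  expect_equal(f2$r2, 1, tolerance = 1e-6)
  expect_lt(f2s$r2, 1 - 1e-3)
  # centers reported in increasing order
  expect_lt(f2$params["c1"], f2$params["c2"])
  expect_error(gaussianModelFit(laminarProfile(layerDepths(5),
                                               rnorm(5)), 2), "depth samples")
})

test_that("two-peak test: null case, detection, and determinism", {
  d <- layerDepths(15)
  # single-Gaussian truth with centers/widths on the search grid: no
  # two-peak evidence
  y1 <- 2 + 1.3 * exp(-(d - d[8])^2 / (2 * (0.1 * diff(range(d)))^2))
  prof1 <- laminarProfile(d, y1, se = rep(0.01, 15))
  r1 <- twoPeakTest(prof1, nBoot = 400, seed = 2)
  expect_lt(r1@r2Diff, 0.01)
  expect_gt(r1@pValue, 0.006)

  # well-separated double Gaussian with small errors: detected
  y2 <- 1 + exp(-(d - 0.2)^2 / (2 * 0.09^2)) +
    0.9 * exp(-(d - 0.75)^2 / (2 * 0.09^2))
  prof2 <- laminarProfile(d, y2, se = rep(0.03, 15))
  r2 <- twoPeakTest(prof2, nBoot = 1000, seed = 3)
  expect_lt(r2@pValue, 0.006)
  expect_gt(r2@r2Diff, 0)

  # seeded determinism
  r2b <- twoPeakTest(prof2, nBoot = 1000, seed = 3)
  expect_identical(r2@pValue, r2b@pValue)

  # too few depth samples for the 7-parameter fit
  expect_error(twoPeakTest(laminarProfile(layerDepths(8), rnorm(8),
                                          se = rep(0.1, 8))), ">= 9")
})

test_that("the two-peak score is invariant under affine rescaling", {
  d <- layerDepths(15)
  set.seed(8)
  y <- 1 + exp(-(d - 0.3)^2 / 0.02) + rnorm(15, 0, 0.05)
  se <- rep(0.05, 15)
  a <- twoPeakTest(laminarProfile(d, y, se = se), nBoot = 50, seed = 4)
  b <- twoPeakTest(laminarProfile(d, 3 * y - 7, se = 3 * se),
                   nBoot = 50, seed = 4)
  expect_equal(a@r2Diff, b@r2Diff, tolerance = 1e-10)
  expect_equal(a@pValue, b@pValue)
})

test_that("contrast correlations report r, p and sign agreement", {
  x <- c(1, 2, 3, 4)
  r <- correlateContrasts(x, x)
  expect_equal(r$r, 1)
  expect_equal(r$sameDirectionFraction, 1)
  r2 <- correlateContrasts(x, -x)
  expect_equal(r2$r, -1)
  expect_equal(r2$sameDirectionFraction, 0)
  expect_error(correlateContrasts(c(1, 1, 1), c(1, 2, 3)), "variance")
  # seeded simulation with known generating correlation 0.8
  set.seed(15)
  n <- 500
  z <- rnorm(n)
  xx <- z + rnorm(n) * sqrt(1 / 0.8^2 - 1)
  r3 <- correlateContrasts(xx, z)
  expect_equal(r3$r, 0.8, tolerance = 0.06)
})

test_that("paired comparisons use the rounded Bonferroni thresholds", {
  a <- c(1, 2, 3, 4)
  same <- groupCompare(a, a, nComparisons = 12)
  expect_equal(same$t, 0)
  expect_false(same$significant)
  expect_equal(groupCompare(a, a + rnorm(4), nComparisons = 12)$threshold,
               0.004)
  expect_equal(groupCompare(a, a + rnorm(4), nComparisons = 8)$threshold,
               0.006)
  expect_error(groupCompare(c(1, 2, 3, 4), c(2, 3, 4, 5)), "zero-variance")
})
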