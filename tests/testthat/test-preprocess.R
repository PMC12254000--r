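test_that("pairwise subtraction: zeros, lengths, and the generator oracle", {
  x <- matrix(rnorm(20), 2, 10)
  same <- cbind(x, x)[, rep(1:10, each = 2) + c(0, 10)]  # control == label
  expect_equal(pairwiseSubtract(same), matrix(0, 2, 10))

  long <- matrix(rnorm(2 * 54), 2, 54)
  expect_identical(ncol(pairwiseSubtract(long)), 27L)
  expect_error(pairwiseSubtract(matrix(1, 2, 5)), "even")

  run <- simulateBreathHoldRun(smallBhPhysiology(3), noiseSd = noiseless,
                               seed = 1, voxelsPerLayer = 2)
  perf <- pairwiseSubtract(contrastSeries(run, "asl"))
  # noiseless perfusion equals the generator's aslDiffOverM0 exactly:
  # reconstruct from the truth at each volume's hypercapnia level
  tr <- groundTruth(run)
  vol <- volumeInfo(run)
  lab <- layerLabels(run)
  for (v in c(1, 10, 30)) {
    rf <- 1 + vol$h[v] * (tr@cbfResponse - 1)
    fs <- forwardSignals(tr, run@acquisition, rf,
                         1 + vol$h[v] * (tr@cbvResponse - 1), 1)
    expect_equal(perf[, v], fs$aslDiffOverM0[lab], tolerance = 1e-12)
  }
})

test_that("detrending removes polynomial trends and restores the mean", {
  expect_equal(detrendRun(rep(3, 20)), rep(3, 20))
  ramp <- seq(0, 10, length.out = 21) - 0  # linear, mean 5
  expect_equal(detrendRun(ramp), rep(5, 21))
  # order-k detrending annihilates any degree-k polynomial (mean restored)
  tt <- seq_len(30)
  coefs <- list(c(2, 0.5), c(2, 0.5, -0.02), c(2, 0.5, -0.02, 1e-3))
  for (k in 1:3) {
    y <- drop(outer(tt, 0:k, `^`) %*% coefs[[k]])
    expect_equal(detrendRun(y, order = k), rep(mean(y), 30),
                 tolerance = 1e-8)
  }
  expect_error(detrendRun(1:5, order = 5), "order")
})

test_that("percentile capping matches the interpolation-quantile oracle", {
  expect_equal(capOutliers(1:10, 25, 75),
               c(3.25, 3.25, 3.25, 4, 5, 6, 7, 7.75, 7.75, 7.75))
  expect_equal(capOutliers(rep(2, 8), 15, 85), rep(2, 8))
  expect_error(capOutliers(numeric(0), 25, 75), "empty")
  expect_error(capOutliers(1:10, 80, 20), "loPct")
})

test_that("capping is idempotent and preserves interior order statistics", {
  set.seed(4)
  for (pair in list(c(15, 85), c(25, 75))) {
    x <- rnorm(60)
    once <- capOutliers(x, pair[1], pair[2])
    # interpolation quantiles shift slightly once mass accumulates at the
    # caps, so idempotency is near-exact rather than exact
    twice <- capOutliers(once, pair[1], pair[2])
    expect_lt(max(abs(twice - once)), 0.05 * sd(x))
    q <- quantile(x, pair / 100, names = FALSE)
    interior <- x > q[1] & x < q[2]
    expect_identical(once[interior], x[interior])
    expect_identical(order(x[interior]), order(once[interior]))
  }
})

test_that("slice deblurring inverts its own blur operator", {
  prof <- sin(seq(0, 3, length.out = 14)) + seq(0, 1, length.out = 14)
  A <- sliceBlurOperator(14)
  blurred <- as.numeric(A %*% prof)
  rec <- svdDeblur(blurred, threshold = 0)
  expect_lt(max(abs(rec - prof)) / max(abs(prof)), 1e-6)
  # infinite T2: no decay, identity operator
  expect_equal(sliceBlurOperator(14, t2Arterial = Inf), diag(14),
               tolerance = 1e-12)
  expect_equal(svdDeblur(blurred, threshold = 0, t2Arterial = Inf), blurred)
  # linear ordering inverts as well
  Al <- sliceBlurOperator(14, ordering = "linear")
  recL <- svdDeblur(as.numeric(Al %*% prof), threshold = 0,
                    ordering = "linear")
  expect_lt(max(abs(recL - prof)), 1e-6)
})

test_that("full truncation yields a smoother-than-input reconstruction", {
  prof <- c(rep(0, 5), 1, rep(0, 8))
  A <- sliceBlurOperator(14)
  blurred <- as.numeric(A %*% prof)
  rec <- svdDeblur(blurred, threshold = 1.0)
  tv <- function(x) sum(abs(diff(x)))
  expect_lte(tv(rec), tv(blurred))
})

test_that("breath-hold delay estimation recovers constructed shifts", {
  p <- bhParadigm()
  tt <- 0:500
  cyc <- p@onDuration + p@offDuration
  reg <- as.numeric((tt - p@leadIn) >= 0 &
                      ((tt - p@leadIn) %% cyc) >= p@offDuration)
  expect_equal(estimateBreathHoldDelay(reg, p, tr = 1), 0)
  shifted <- c(rep(0, 5), reg[1:(length(reg) - 5)])
  expect_equal(estimateBreathHoldDelay(shifted, p, tr = 1), 5)
  expect_error(estimateBreathHoldDelay(rep(1, 100), p, tr = 1), "flat")
  set.seed(9)
  expect_error(estimateBreathHoldDelay(rnorm(200), p, tr = 1), "reliable")
})
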