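test_that("flat scenario is the identity physiology", {
  phys <- makePhysiology(8, "flat")
  expect_equal(length(unique(phys@baselineCbf)), 1L)
  expect_true(all(phys@cbfResponse == 1))
  expect_true(all(phys@cmro2Response == 1))
})

test_that("task_two_peak places exactly two local CBF maxima over depth", {
  phys <- makePhysiology(15, "task_two_peak")
  y <- phys@cbfResponse
  nMax <- sum(vapply(2:14, function(i) y[i] > y[i - 1] && y[i] > y[i + 1],
                     logical(1)))
  expect_identical(nMax, 2L)
  # deep peak in the deep third, superficial peak in the superficial third
  d <- layerDepths(15)
  peaks <- which(vapply(2:14, function(i) y[i] > y[i - 1] && y[i] > y[i + 1],
                        logical(1))) + 1L
  expect_lt(d[peaks[1]], 1 / 3)
  expect_gt(d[peaks[2]], 2 / 3)
})

test_that("bh_default beta increases monotonically from deep to superficial", {
  phys <- makePhysiology(8, "bh_default")
  expect_true(all(diff(phys@davisBeta) > 0))
})

test_that("physiology construction validates its inputs", {
  expect_error(makePhysiology(1, "flat"), "nLayers")
  expect_error(makePhysiology(8, "no_such_scenario"))
  expect_error(layerPhysiology(8, baselineCbv = 1.2), "baselineCbv")
  expect_error(layerPhysiology(8, davisBeta = -1), "davisBeta")
  expect_error(layerPhysiology(8, cbfResponse = 0), "positive")
})

test_that("forward signals reduce to baseline at unit ratios", {
  phys <- makePhysiology(8, "flat")
  fs <- forwardSignals(phys, rCbf = 1, rCbv = 1, rCmro2 = 1)
  expect_equal(fs$deltaBold, rep(0, 8))
  expect_equal(fs$vaso, rep(1, 8))
  expect_equal(fs$bold, rep(1, 8))
  # the baseline ASL difference matches the closed-form oracle
  expect_equal(oracleCbf(fs$aslDiffOverM0), phys@baselineCbf,
               tolerance = 1e-12)
})

test_that("forward BOLD matches the Davis closed form", {
  phys <- layerPhysiology(2, davisM = 0.055, davisBeta = 1.10)
  fs <- forwardSignals(phys, rCbf = 1.45, rCbv = 1.19, rCmro2 = 1)
  expect_equal(fs$deltaBold, rep(0.055 * (1 - 1.19 * 1.45^-1.1), 2),
               tolerance = 1e-12)
  expect_equal(fs$deltaBold[1], 0.01151, tolerance = 1e-3)
  # VASO/BOLD division removes the contamination exactly at unchanged CBV
  fs2 <- forwardSignals(phys, rCbf = 1.45, rCbv = 1, rCmro2 = 1)
  expect_equal(fs2$vaso / (1 + fs2$deltaBold), rep(1, 2), tolerance = 1e-12)
  expect_error(forwardSignals(phys, rCbf = -1), "positive")
})

test_that("breath-hold simulation matches the calibration problem size", {
  run <- simulateBreathHoldRun(smallBhPhysiology(4), noiseSd = noiseless,
                               seed = 1, voxelsPerLayer = 2)
  expect_identical(ncol(contrastSeries(run, "vaso")), 54L)   # 2 runs x 27
  expect_identical(ncol(contrastSeries(run, "asl")), 108L)
  expect_identical(ncol(contrastSeries(run, "bold")), 108L)
  expect_identical(nrow(volumeInfo(run)), 54L)
})

test_that("null paradigm gives constant signals at baseline", {
  phys <- makePhysiology(4, "flat")   # unit responses: h cannot act
  run <- simulateBreathHoldRun(phys, noiseSd = noiseless, seed = 1,
                               voxelsPerLayer = 2, cbvJitterSd = 0)
  expect_equal(max(contrastSeries(run, "vaso")) -
                 min(contrastSeries(run, "vaso")), 0)
  expect_equal(max(contrastSeries(run, "bold")) -
                 min(contrastSeries(run, "bold")), 0)
  perf <- pairwiseSubtract(contrastSeries(run, "asl"))
  expect_equal(max(perf) - min(perf), 0)
})

test_that("identical seeds give bit-identical runs", {
  phys <- smallBhPhysiology(4)
  r1 <- simulateBreathHoldRun(phys, seed = 11, voxelsPerLayer = 3)
  r2 <- simulateBreathHoldRun(phys, seed = 11, voxelsPerLayer = 3)
  expect_identical(contrastSeries(r1, "asl"), contrastSeries(r2, "asl"))
  expect_identical(contrastSeries(r1, "vaso"), contrastSeries(r2, "vaso"))
  expect_identical(contrastSeries(r1, "bold"), contrastSeries(r2, "bold"))
  expect_identical(volumeInfo(r1), volumeInfo(r2))
  r3 <- simulateBreathHoldRun(phys, seed = 12, voxelsPerLayer = 3)
  expect_false(identical(contrastSeries(r1, "bold"),
                         contrastSeries(r3, "bold")))
})

test_that("task run timing: 5 cycles of 48/48 s give 20 ASL pairs and 40 BOLD volumes", {
  run <- simulateTaskRun(makePhysiology(4, "task_two_peak"),
                         noiseSd = noiseless, seed = 1, voxelsPerLayer = 2)
  expect_identical(ncol(contrastSeries(run, "vaso")), 20L)
  expect_identical(ncol(contrastSeries(run, "asl")), 40L)
  expect_identical(ncol(contrastSeries(run, "bold")), 40L)
  expect_identical(sum(volumeInfo(run)$condition == "task"), 10L)
})

test_that("unit response ratios give equal task and rest means", {
  run <- simulateTaskRun(makePhysiology(4, "flat"), noiseSd = noiseless,
                         seed = 1, voxelsPerLayer = 2)
  vol <- volumeInfo(run)
  vaso <- contrastSeries(run, "vaso")
  expect_equal(rowMeans(vaso[, vol$condition == "task"]),
               rowMeans(vaso[, vol$condition == "rest"]))
})

test_that("injected drift is removed exactly by detrending (generator oracle)", {
  phys <- makePhysiology(3, "flat")
  clean <- simulateTaskRun(phys, noiseSd = noiseless, seed = 1,
                           voxelsPerLayer = 2)
  drifted <- simulateTaskRun(phys, noiseSd = noiseless, seed = 1,
                             voxelsPerLayer = 2, driftSlope = 1e-4)
  det <- detrendRun(contrastSeries(drifted, "vaso"))
  ref <- contrastSeries(clean, "vaso")
  # the drift-free shape is restored exactly; the preserved mean is the
  # observed one (the drift's average offset is not identifiable)
  expect_equal(det - rowMeans(det), ref - rowMeans(ref), tolerance = 1e-10)
  expect_lt(max(abs(det - rowMeans(det) -
                      (ref - rowMeans(ref)))), 1e-10)
})

test_that("outlier spikes are flagged in the metadata", {
  run <- simulateTaskRun(makePhysiology(3, "flat"), noiseSd = noiseless,
                         seed = 5, voxelsPerLayer = 2, outlierRate = 0.3)
  vol <- volumeInfo(run)
  expect_true(any(vol$outlier))
  vaso <- contrastSeries(run, "vaso")
  spiked <- which(vol$outlier)[1]
  expect_gt(vaso[1, spiked], 1)  # spike amplitude added on top of signal
})

test_that("ramped hypercapnia spans a range and rests keep residual levels", {
  run <- simulateBreathHoldRun(smallBhPhysiology(3), seed = 2,
                               voxelsPerLayer = 2)
  vol <- volumeInfo(run)
  hBh <- vol$h[vol$condition == "bh"]
  expect_gt(max(hBh) - min(hBh), 0.1)        # cycle-to-cycle variation
  hRest <- vol$h[vol$condition == "rest"]
  expect_true(any(hRest > 0.05))             # incomplete recovery
  expect_true(all(vol$h >= 0 & vol$h <= 1))
  # lead-in volumes are exactly hypercapnia-free
  expect_true(all(vol$h[leadInIndex(vol)] == 0))
})

test_that("calibration Jacobian at truth has full numerical rank (bh_default)", {
  run <- simulateBreathHoldRun(makePhysiology(8, "bh_default"),
                               noiseSd = noiseless, seed = 3,
                               voxelsPerLayer = 2)
  inp <- breathHoldInputs(run)
  anchor <- leadInIndex(inp$volumes)
  l <- 4L
  tr <- groundTruth(run)
  cbf <- inp$cbf[l, ]; vaso <- inp$vaso[l, ]; bold <- inp$bold[l, ]
  vaso0 <- mean(vaso[anchor])
  th0 <- c(tr@davisM[l], tr@davisBeta[l], tr@baselineCbf[l], vaso0, 1)
  res <- function(p) {
    rf <- cbf / p[3]
    rv <- (1 - (vaso / p[4]) * (1 - 0.055)) / 0.055
    c(bold - p[5] * (1 + p[1] * (1 - rv * rf^(-p[2]))),
      rf[anchor] - 1, vaso[anchor] / p[4] - 1)
  }
  J <- vapply(1:5, function(j) {
    dp <- th0; h <- th0[j] * 1e-6; dp[j] <- dp[j] + h
    (res(dp) - res(th0)) / h
  }, numeric(length(res(th0))))
  sv <- svd(J)$d
  expect_identical(sum(sv > 1e-8 * sv[1]), 5L)
})
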