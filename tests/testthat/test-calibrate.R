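test_that("Davis forward model: special values and monotonicity", {
  expect_equal(davisForward(0.055, 1.1, 1, 1, 1), 0)
  expect_equal(davisForward(0.055, 1.10, 1.45, 1.19),
               oracleDavis(0.055, 1.10, 1.45, 1.19), tolerance = 1e-12)
  expect_equal(davisForward(0.055, 1.10, 1.45, 1.19), 0.01151,
               tolerance = 1e-3)
  # constructed null: bracket vanishes when r_cbv = r_cbf^beta / r_cmro2^beta
  rf <- 1.4; beta <- 1.2; rm <- 1.1
  expect_equal(davisForward(0.1, beta, rf, rf^beta / rm^beta, rm), 0,
               tolerance = 1e-12)
  # strict monotonicity at M > 0
  base <- davisForward(0.06, 1.1, 1.4, 1.2, 1.1)
  expect_lt(davisForward(0.06, 1.1, 1.4, 1.2, 1.2), base)
  expect_lt(davisForward(0.06, 1.1, 1.4, 1.3, 1.1), base)
  expect_gt(davisForward(0.06, 1.1, 1.5, 1.2, 1.1), base)
})

test_that("CMRO2 inversion is the exact inverse of the forward model", {
  expect_equal(cmro2Ratio(0, 1, 1, m = 0.055, beta = 1.1), 1)
  db <- davisForward(0.055, 1.10, 1.45, 1.19, rCmro2 = 1.2)
  expect_equal(cmro2Ratio(db, 1.45, 1.19, 0.055, 1.10), 1.2,
               tolerance = 1e-10)
  expect_error(cmro2Ratio(0.2, 1, 1, m = 0.055, beta = 1.1), "ceiling")
  # roundtrip identity over a parameter grid
  set.seed(7)
  grid <- expand.grid(m = c(0.02, 0.08, 0.2), beta = c(0.5, 1.1, 2),
                      rf = c(0.8, 1.3, 1.9), rv = c(0.9, 1.2, 1.8),
                      rm = c(0.85, 1, 1.4))
  db <- with(grid, davisForward(m, beta, rf, rv, rm))
  back <- with(grid, cmro2Ratio(db, rf, rv, m, beta))
  expect_equal(back, grid$rm, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Grubb exponent estimation through the origin", {
  expect_equal(grubbAlpha(c(1.3, 1.7), c(1.3, 1.7)), 1)
  rf <- c(1.2, 1.5, 2)
  expect_equal(grubbAlpha(rf, rf^0.38), 0.38, tolerance = 1e-12)
  expect_equal(grubbAlpha(c(1.5, 2), c(1.5^0.5, 2^0.5)), 0.5,
               tolerance = 1e-12)
  expect_error(grubbAlpha(c(1, 1), c(1, 1)), "undefined")
})

test_that("venous CBV adjustment applies the power law", {
  expect_equal(venousCbvAdjust(1), 1)
  expect_equal(venousCbvAdjust(1.2), 1.2^0.53)
  expect_equal(venousCbvAdjust(1.2), 1.1015, tolerance = 1e-4)
  expect_error(venousCbvAdjust(-1), "ratio")
})

test_that("joint calibration recovers all five unknowns from noiseless runs", {
  run <- simulateBreathHoldRun(makePhysiology(8, "bh_default"),
                               noiseSd = noiseless, seed = 3,
                               voxelsPerLayer = 2)
  inp <- breathHoldInputs(run)
  expect_identical(ncol(inp$cbf), 54L)
  anchor <- leadInIndex(inp$volumes)
  tr <- groundTruth(run)
  for (l in c(1L, 4L, 8L)) {
    f <- fitBreathHoldCalibration(inp$cbf[l, ], inp$vaso[l, ],
                                  inp$bold[l, ], baselineIndex = anchor)
    expect_true(f@converged)
    expect_lt(abs(f@m / tr@davisM[l] - 1), 1e-4)
    expect_lt(abs(f@beta / tr@davisBeta[l] - 1), 1e-4)
    expect_lt(abs(f@baselineCbf / tr@baselineCbf[l] - 1), 1e-4)
    expect_lt(abs(f@baselineBold - 1), 1e-4)
    expect_lt(f@rmse, 1e-8)
  }
})

test_that("calibration signals degenerate constant input", {
  expect_error(
    fitBreathHoldCalibration(rep(50, 20), rep(1, 20), rep(1, 20)),
    "identifiable")
  expect_error(
    fitBreathHoldCalibration(rep(50, 5), runif(5), runif(5)),
    "10 time points")
})

test_that("fitted CMRO2 during breath-hold is unity (self-consistency)", {
  run <- simulateBreathHoldRun(makePhysiology(8, "bh_default"),
                               noiseSd = noiseless, seed = 5,
                               voxelsPerLayer = 2)
  inp <- breathHoldInputs(run)
  anchor <- leadInIndex(inp$volumes)
  l <- 5L
  f <- fitBreathHoldCalibration(inp$cbf[l, ], inp$vaso[l, ], inp$bold[l, ],
                                baselineIndex = anchor)
  rf <- inp$cbf[l, ] / f@baselineCbf
  rv <- (1 - (inp$vaso[l, ] / f@baselineVaso) * (1 - 0.055)) / 0.055
  db <- inp$bold[l, ] / f@baselineBold - 1
  on <- inp$volumes$condition == "bh"
  rm <- cmro2Ratio(db[on], rf[on], rv[on], f@m, f@beta)
  expect_equal(mean(rm), 1, tolerance = 1e-6)
})

test_that("calibration bias vanishes as measurement noise shrinks", {
  phys <- smallBhPhysiology(4)
  set.seed(31)
  errs <- replicate(8, {
    r <- simulateBreathHoldRun(phys,
                               noiseSd = c(0.002, 0.005, 0.005) / 20,
                               seed = sample.int(1e6, 1), voxelsPerLayer = 50)
    i <- breathHoldInputs(r)
    a <- leadInIndex(i$volumes)
    f <- fitBreathHoldCalibration(i$cbf[2, ], i$vaso[2, ], i$bold[2, ],
                                  baselineIndex = a)
    c(abs(f@beta - 1.10), abs(f@m / 0.055 - 1))
  })
  expect_lt(median(errs[1, ]), 0.02)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("baseline-CBV sensitivity grid reruns the fit per assumed value", {
  run <- simulateBreathHoldRun(smallBhPhysiology(3), noiseSd = noiseless,
                               seed = 9, voxelsPerLayer = 2)
  inp <- breathHoldInputs(run)
  a <- leadInIndex(inp$volumes)
  sens <- calibrationSensitivity(inp$cbf[2, ], inp$vaso[2, ], inp$bold[2, ],
                                 baselineIndex = a)
  expect_identical(nrow(sens), 3L)
  expect_equal(sens$cbvRest, 0.055 * c(0.75, 1, 1.25))
  # the assumed baseline CBV changes the fitted M
  expect_false(isTRUE(all.equal(sens$m[1], sens$m[3])))
})
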