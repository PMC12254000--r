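test_that("one-compartment CBF matches the closed form and is linear", {
  k <- quantConstants()
  expect_equal(cbfOneCompartment(0, k), 0)
  expect_equal(cbfOneCompartment(0.005, k), oracleCbf(0.005),
               tolerance = 1e-12)
  expect_equal(cbfOneCompartment(0.005, k), 31.4, tolerance = 1e-2)
  # linearity in the normalized difference signal
  x <- runif(10, 0, 0.01)
  expect_equal(cbfOneCompartment(3 * x, k), 3 * cbfOneCompartment(x, k))
  # generator roundtrip at baseline
  phys <- makePhysiology(4, "flat")
  fs <- forwardSignals(phys, rCbf = 1, rCbv = 1)
  expect_equal(cbfOneCompartment(fs$aslDiffOverM0, k), phys@baselineCbf,
               tolerance = 1e-9)
})

test_that("percent BOLD change and task responses behave", {
  expect_equal(boldChange(1, 1), 0)
  expect_equal(boldChange(1.02, 1.00), 2)
  expect_error(boldChange(1, 0), "positive")
  tr <- taskResponse(c(2, 2), c(1, 2))
  expect_equal(tr$delta, c(1, 0))
  expect_equal(tr$percent, c(100, 0))
  expect_error(taskResponse(1, 0), "zero")
})

test_that("VASO BOLD-correction cancels the contamination", {
  # constant BOLD at its rest mean leaves VASO unchanged
  vaso <- matrix(runif(10, 0.9, 1), 1)
  bold <- matrix(1, 1, 10)
  expect_equal(vasoBoldCorrect(vaso, bold), vaso)
  # exact cancellation of a 2% BOLD factor against a known rest reference
  expect_equal(vasoBoldCorrect(0.95 * 1.02, 1.02, boldRestMean = 1), 0.95)
  expect_error(vasoBoldCorrect(matrix(1, 1, 4), matrix(1, 1, 7)),
               "misaligned")
  # generator oracle: corrected VASO equals the pure-VASO signal
  run <- simulateBreathHoldRun(smallBhPhysiology(3), noiseSd = noiseless,
                               seed = 1, voxelsPerLayer = 2,
                               cbvJitterSd = 0)
  vol <- volumeInfo(run)
  corrected <- vasoBoldCorrect(contrastSeries(run, "vaso"),
                               contrastSeries(run, "bold"),
                               restIndex = which(vol$condition == "rest"))
  tr <- groundTruth(run)
  lab <- layerLabels(run)
  for (v in c(2, 15, 40)) {
    rv <- 1 + vol$h[v] * (tr@cbvResponse - 1)
    pure <- (1 - tr@baselineCbv * rv) / (1 - tr@baselineCbv)
    # rest-mean normalization is a per-voxel constant; compare ratios
    ratio <- corrected[, v] / corrected[, 1]
    expect_equal(ratio, pure[lab] / 1, tolerance = 1e-12)
  }
})

test_that("VASO ratio converts to CBV ratio per the blood-nulling relation", {
  expect_equal(cbvRatio(1)$ratio, 1)
  expect_equal(cbvRatio(1)$percentChange, 0)
  out <- cbvRatio(0.98, 0.055)
  expect_equal(out$ratio, (1 - 0.98 * 0.945) / 0.055, tolerance = 1e-12)
  expect_equal(out$ratio, 1.3436, tolerance = 1e-4)
  expect_equal(out$percentChange, 34.4, tolerance = 1e-2)
  expect_error(cbvRatio(2, 0.055), "physical")
  # inverse of the forward relation over the physical range
  for (rv in c(0.5, 0.9, 1, 1.5, 3)) {
    vasoRatio <- (1 - 0.055 * rv) / (1 - 0.055)
    expect_equal(cbvRatio(vasoRatio, 0.055)$ratio, rv, tolerance = 1e-12)
  }
})

test_that("condition means exclude transition volumes", {
  vol <- data.frame(run = 1, condition = c("rest", "rest", "task", "task",
                                           "rest", "rest"))
  x <- matrix(1:6, 1)
  # dropTransition = 1 drops volumes 1 (run start), 3, 5
  expect_equal(conditionMeans(x, vol, "task", dropTransition = 1), 4)
  expect_equal(conditionMeans(x, vol, "task", dropTransition = 0), 3.5)
  expect_error(conditionMeans(x, vol, "bh"), "no volumes")
})

test_that("full noiseless chain recovers every generating quantity", {
  # breath-hold plateau: quantified responses equal the generating ratios
  for (scen in c("bh_default", "task_two_peak")) {
    if (scen == "bh_default") {
      run <- simulateBreathHoldRun(makePhysiology(8, scen),
                                   paradigm = bhParadigm("plateau"),
                                   noiseSd = noiseless, seed = 1, nRuns = 1,
                                   voxelsPerLayer = 3, cbvJitterSd = 0)
      cond <- "bh"
    } else {
      run <- simulateTaskRun(makePhysiology(8, scen), noiseSd = noiseless,
                             seed = 1, voxelsPerLayer = 3)
      cond <- "task"
    }
    tr <- groundTruth(run)
    q <- quantifyRun(run, taskCondition = cond, dropTransition = 0)
    expect_equal(q$cbfRest, tr@baselineCbf, tolerance = 1e-6)
    expect_equal(q$cbfPercent, (tr@cbfResponse - 1) * 100, tolerance = 1e-6)
    expect_equal(q$cbvRatio, tr@cbvResponse, tolerance = 1e-6)
    expect_equal(q$boldPercent,
                 100 * oracleDavis(tr@davisM, tr@davisBeta, tr@cbfResponse,
                                   tr@cbvResponse, tr@cmro2Response),
                 tolerance = 1e-6)
  }
})

test_that("cmro2Profile inverts the Davis model along the chain", {
  run <- simulateTaskRun(makePhysiology(8, "task_two_peak"),
                         noiseSd = noiseless, seed = 1, voxelsPerLayer = 3)
  tr <- groundTruth(run)
  q <- quantifyRun(run, dropTransition = 0)
  prof <- cmro2Profile(q, m = tr@davisM, beta = tr@davisBeta)
  expect_equal(prof$cmro2Ratio, tr@cmro2Response, tolerance = 1e-6)
})
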