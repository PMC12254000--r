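#' Davis-model forward BOLD change
#'
#' The calibrated-BOLD (Davis) model relates the fractional BOLD signal
#' change to task/rest ratios of CMRO2, CBV and CBF:
#' \deqn{\Delta BOLD = M (1 - r_{CMRO2}^{\beta} \, r_{CBV} \, r_{CBF}^{-\beta})}
#' With `rCmro2 = 1` this is the simplified hypercapnia form used during
#' breath-hold calibration. All arguments are vectorized.
#'
#' @param m Davis M, the maximal attainable BOLD change (fraction >= 0).
#' @param beta Davis susceptibility exponent (> 0).
#' @param rCbf CBF task/rest ratio (> 0).
#' @param rCbv CBV task/rest ratio (> 0).
#' @param rCmro2 CMRO2 task/rest ratio (> 0); default 1.
#' @return fractional BOLD change (not percent).
#' @examples
#' davisForward(0.055, 1.10, rCbf = 1.45, rCbv = 1.19)  # ~0.0115
#' @seealso [cmro2Ratio()] for the inverse.
#' @export
davisForward <- function(m, beta, rCbf, rCbv, rCmro2 = 1) {
  stopIfNot(all(m >= 0), "m must be >= 0")
  stopIfNot(all(beta > 0), "beta must be > 0")
  stopIfNot(all(rCbf > 0) && all(rCbv > 0) && all(rCmro2 > 0),
            "all ratios must be > 0")
  m * (1 - rCmro2^beta * rCbv * rCbf^(-beta))
}

#' Invert the Davis model for the CMRO2 ratio
#'
#' Exact inverse of [davisForward()]:
#' \deqn{r_{CMRO2} = \left[(1 - \Delta BOLD / M)\, r_{CBF}^{\beta} / r_{CBV}\right]^{1/\beta}}
#'
#' @param deltaBold fractional BOLD change (not percent).
#' @param rCbf CBF task/rest ratio.
#' @param rCbv CBV task/rest ratio.
#' @param m,beta Davis parameters (e.g. from a [CalibrationFit-class]).
#' @return CMRO2 task/rest ratio.
#' @examples
#' db <- davisForward(0.055, 1.10, 1.45, 1.19, rCmro2 = 1.2)
#' cmro2Ratio(db, 1.45, 1.19, m = 0.055, beta = 1.10)  # 1.2
#' @export
cmro2Ratio <- function(deltaBold, rCbf, rCbv, m, beta) {
  stopIfNot(all(m > 0), "m must be > 0 to invert the model")
  bracket <- (1 - deltaBold / m) * rCbf^beta / rCbv
  if (any(bracket <= 0))
    stop("BOLD change exceeds the Davis-model ceiling M; ",
         "CMRO2 ratio is undefined", call. = FALSE)
  bracket^(1 / beta)
}

#' Estimate the Grubb exponent from paired CBF/CBV ratios
#'
#' Grubb's power law couples blood volume to flow, CBV ~ CBF^alpha. Given
#' paired task/rest ratios the exponent is the least-squares slope of
#' log(rCbv) on log(rCbf) through the origin (both logs vanish at ratio 1).
#'
#' @param rCbf CBF task/rest ratios.
#' @param rCbv CBV task/rest ratios (same length).
#' @return the exponent alpha.
#' @examples
#' grubbAlpha(c(1.5, 2), c(1.5^0.38, 2^0.38))  # 0.38
#' @export
grubbAlpha <- function(rCbf, rCbv) {
  stopIfNot(length(rCbf) == length(rCbv), "inputs must have equal length")
  stopIfNot(all(rCbf > 0) && all(rCbv > 0), "ratios must be positive")
  x <- log(rCbf); y <- log(rCbv)
  keep <- x != 0
  if (sum(keep) < 1)
    stop("all rCbf equal 1: slope through the origin is undefined",
         call. = FALSE)
  sum(x[keep] * y[keep]) / sum(x[keep]^2)
}

#' Venous blood-volume adjustment
#'
#' The BOLD signal is driven by the venous compartment of CBV, while VASO
#' measures total CBV. A power-law rescaling of the total-CBV task/rest
#' ratio approximates the venous ratio: `rCbvVenous = rCbvTotal^exponent`
#' with a default exponent of 0.53.
#'
#' @param rCbvTotal total-CBV task/rest ratio (> 0).
#' @param exponent venous scaling exponent.
#' @return venous-CBV task/rest ratio.
#' @examples
#' venousCbvAdjust(1.2)  # 1.2^0.53 ~ 1.1015
#' @export
venousCbvAdjust <- function(rCbvTotal, exponent = 0.53) {
  stopIfNot(all(rCbvTotal > 0), "ratio must be > 0")
  rCbvTotal^exponent
}

#' Joint five-unknown breath-hold calibration
#'
#' Fits the simplified Davis model (CMRO2 unchanged during hypercapnia) to
#' co-sampled CBF, BOLD-corrected VASO and BOLD time series spanning rest and
#' variable-depth breath-hold, estimating M, beta and the three baseline
#' signals simultaneously. Because residual hypercapnia contaminates nominal
#' rest periods, no time point is trusted as a clean baseline; instead the
#' baselines are free parameters and the objective is the raw-BOLD residual
#' \deqn{\sum_t \left[ BOLD(t) - b_0 \left(1 + M (1 - r_{CBV}(t)\, r_{CBF}(t)^{-\beta})\right) \right]^2}
#' with `rCbf(t) = cbf(t)/cbf0` and `rCbv(t)` derived from
#' `vaso(t)/vaso0` through the VASO-to-CBV conversion at `cbvRest`.
#'
#' For fixed beta the predicted BOLD depends on (M, cbf0, vaso0, bold0) only
#' through three linear coefficients, so the BOLD residual alone leaves a
#' one-dimensional family of exact fits (M trades against the baselines).
#' The fit therefore accepts `baselineIndex`: time points known to be
#' hypercapnia-free — the volumes acquired before the first breath-hold of
#' each run, where no residual hypercapnia can exist. At those points the
#' model requires r_CBF = r_CBV = 1, contributing anchor residuals
#' `(cbf(t)/cbf0 - 1)` and `(vaso(t)/vaso0 - 1)` that pin the baseline
#' scale and make all five unknowns identifiable. Later rest blocks remain
#' unconstrained (they may carry residual hypercapnia). Without
#' `baselineIndex` only beta and vaso0 are well determined.
#'
#' Minimization uses Levenberg-Marquardt (\pkg{minpack.lm}) with box
#' constraints, multi-started from a small grid of beta values and
#' data-driven baseline guesses; the best local optimum is returned.
#'
#' @param cbf CBF time series, ml/100g/min (one value per ASL/VASO volume).
#' @param vaso BOLD-corrected VASO time series (same sampling).
#' @param bold BOLD time series resampled to the ASL/VASO volumes (use the
#'   concurrent BOLD volume).
#' @param cbvRest baseline CBV in ml/ml.
#' @param baselineIndex indices of hypercapnia-free time points (e.g. from
#'   [leadInIndex()]), or `NULL` for the unanchored objective.
#' @param anchorWeight weight of the anchor residuals relative to the
#'   relative-BOLD residual scale.
#' @param betaStarts multi-start grid for beta.
#' @param bounds list with elements `m` (c(lo, hi)), `beta`, and
#'   `baselineFactor` — baselines are constrained to
#'   `baselineFactor * median(data)`.
#' @param maxIter maximum optimizer iterations per start.
#' @return a [CalibrationFit-class].
#' @examples
#' phys <- makePhysiology(8, "bh_default")
#' run <- simulateBreathHoldRun(phys, noiseSd = c(0, 0, 0), seed = 1)
#' inp <- breathHoldInputs(run)
#' fitBreathHoldCalibration(inp$cbf[5, ], inp$vaso[5, ], inp$bold[5, ])
#' @export
fitBreathHoldCalibration <- function(cbf, vaso, bold,
                                     cbvRest = 0.055,
                                     baselineIndex = NULL,
                                     anchorWeight = 1,
                                     betaStarts = c(0.8, 1.0, 1.3),
                                     bounds = list(
                                       m = c(0, 0.5),
                                       beta = c(0.3, 3),
                                       baselineFactor = c(0.5, 2)
                                     ),
                                     maxIter = 2000) {
  n <- length(cbf)
  stopIfNot(length(vaso) == n && length(bold) == n,
            "cbf, vaso and bold must be co-sampled (equal lengths)")
  stopIfNot(n >= 10, "at least 10 time points are required")
  if (stats::sd(cbf) < 1e-12 * abs(mean(cbf)) &&
      stats::sd(vaso) < 1e-12 * abs(mean(vaso)))
    stop("constant CBF and VASO series: the five unknowns are not ",
         "identifiable", call. = FALSE)

  medBold <- stats::median(bold)
  resid <- function(p) {
    m <- p[1]; beta <- p[2]; cbf0 <- p[3]; vaso0 <- p[4]; bold0 <- p[5]
    rCbf <- cbf / cbf0
    rCbv <- (1 - (vaso / vaso0) * (1 - cbvRest)) / cbvRest
    # keep the model evaluable when the optimizer wanders out of the
    # physical range; large penalty residuals steer it back
    bad <- rCbf <= 0 | rCbv <= 0
    pred <- bold0 * (1 + m * (1 - ifelse(bad, 1, rCbv * rCbf^(-beta))))
    r <- bold - pred
    r[bad] <- r[bad] + 1e3
    if (!is.null(baselineIndex)) {
      r <- c(r, anchorWeight * medBold * (rCbf[baselineIndex] - 1),
             anchorWeight * medBold * (vaso[baselineIndex] / vaso0 - 1))
    }
    r
  }

  medCbf <- stats::median(cbf)
  medVaso <- stats::median(vaso)
  medBold <- stats::median(bold)
  lower <- c(bounds$m[1], bounds$beta[1],
             bounds$baselineFactor[1] * c(medCbf, medVaso, medBold))
  upper <- c(bounds$m[2], bounds$beta[2],
             bounds$baselineFactor[2] * c(medCbf, medVaso, medBold))

  # data-driven baseline guesses: rest should be the low-CBF end
  cbf0Guess <- c(stats::quantile(cbf, 0.1, names = FALSE), medCbf)
  best <- NULL
  for (b0 in betaStarts) {
    for (f0 in cbf0Guess) {
      start <- pmin(pmax(c(0.05, b0, f0, stats::quantile(vaso, 0.9,
                                                         names = FALSE),
                           stats::quantile(bold, 0.1, names = FALSE)),
                         lower), upper)
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = start, lower = lower, upper = upper, fn = resid,
          control = minpack.lm::nls.lm.control(
            maxiter = min(maxIter, 1024), ftol = 1e-12, ptol = 1e-12)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
  }
  if (is.null(best))
    stop("breath-hold calibration failed to converge from any start",
         call. = FALSE)
  p <- best$par
  new("CalibrationFit",
    m = p[1], beta = p[2], baselineCbf = p[3], baselineVaso = p[4],
    baselineBold = p[5],
    rmse = sqrt(sum(best$fvec[seq_len(n)]^2) / n),
    converged = best$info %in% 1:4,
    nPoints = as.integer(n),
    cbvRest = cbvRest
  )
}

#' Indices of guaranteed hypercapnia-free volumes
#'
#' Returns the (global) indices of the ASL/VASO volumes acquired before the
#' first breath-hold block of each run: residual hypercapnia from earlier
#' blocks cannot exist there, so these volumes anchor the baseline scale in
#' [fitBreathHoldCalibration()].
#'
#' @param volumes per-volume metadata (`volumeInfo(run)` or the `volumes`
#'   element of [breathHoldInputs()]).
#' @return integer vector of volume indices.
#' @export
leadInIndex <- function(volumes) {
  idx <- integer()
  for (r in unique(volumes$run)) {
    rows <- which(volumes$run == r)
    pre <- cumsum(volumes$condition[rows] != "rest") == 0
    idx <- c(idx, rows[pre])
  }
  idx
}

#' Sensitivity of fitted parameters to the assumed baseline CBV
#'
#' Re-runs the breath-hold calibration over a grid of assumed baseline CBV
#' values and reports the fitted parameters for each, quantifying how an
#' error in the assumed 0.055 ml/ml propagates into M, beta and derived
#' CMRO2 ratios.
#'
#' @param cbf,vaso,bold co-sampled series as in [fitBreathHoldCalibration()].
#' @param cbvRestGrid grid of assumed baseline CBV values.
#' @param ... further arguments to [fitBreathHoldCalibration()].
#' @return data.frame with one row per grid value: `cbvRest`, `m`, `beta`,
#'   `baselineCbf`, `rmse`.
#' @export
calibrationSensitivity <- function(cbf, vaso, bold,
                                   cbvRestGrid = 0.055 * c(0.75, 1, 1.25),
                                   ...) {
  rows <- lapply(cbvRestGrid, function(v) {
    f <- fitBreathHoldCalibration(cbf, vaso, bold, cbvRest = v, ...)
    data.frame(cbvRest = v, m = f@m, beta = f@beta,
               baselineCbf = f@baselineCbf, rmse = f@rmse)
  })
  do.call(rbind, rows)
}
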