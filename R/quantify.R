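# Conversion of preprocessed signals to physiological quantities.

# Closed-form one-compartment scaling: CBF per unit of (deltaM / M0).
# Shared by quantification and the forward generator (exact inverse pair).
cbfPerUnitPerfusion <- function(k) {
  6000 * k$lambdaPartition * exp(k$postLabelingDelay / k$t1Blood) /
    (2 * k$labelingEfficiency * k$bsInversionEfficiency * k$t1Blood *
       (1 - exp(-k$labelingDuration / k$t1Blood)))
}

#' One-compartment CBF quantification for pCASL
#'
#' Converts the M0-normalized perfusion-weighted difference signal to CBF in
#' ml/100g/min with the single-compartment model:
#' \deqn{CBF = \frac{6000\,\lambda\,(\Delta M/M_0)\,e^{PLD/T_{1b}}}
#'   {2\,\alpha_{label}\,\alpha_{BS}\,T_{1b}\,(1 - e^{-LD/T_{1b}})}}
#' where the factor 6000 converts ml/g/s to ml/100g/min. With the default
#' constants (T1b 2.1 s, lambda 0.9 ml/g, labeling efficiency 82.1%,
#' background suppression 95%, LD 1.28 s, PLD 1.16 s) a difference signal of
#' 0.5% of M0 corresponds to about 31.4 ml/100g/min.
#'
#' @param perfusionOverM0 control-minus-label difference normalized to M0
#'   (vector or matrix; the model is linear, so shape is preserved).
#' @param k constants from [quantConstants()].
#' @return CBF in ml/100g/min, same shape as the input.
#' @examples
#' cbfOneCompartment(0.005, quantConstants())
#' @export
cbfOneCompartment <- function(perfusionOverM0, k = quantConstants()) {
  stopIfNot(k$t1Blood > 0, "t1Blood must be positive")
  perfusionOverM0 * cbfPerUnitPerfusion(k)
}

#' Percent BOLD signal change
#'
#' `(task - rest) / rest * 100`, elementwise.
#'
#' @param boldTask task-condition BOLD signal (vector/matrix).
#' @param boldRest rest-condition BOLD signal (> 0).
#' @return percent signal change.
#' @export
boldChange <- function(boldTask, boldRest) {
  stopIfNot(all(boldRest > 0), "rest BOLD must be positive")
  (boldTask - boldRest) / boldRest * 100
}

#' BOLD-correct a VASO time series
#'
#' VASO carries a multiplicative BOLD contamination; dividing by the
#' concurrent BOLD signal (normalized to its rest mean) removes it. BOLD is
#' sampled at half the ASL/VASO volume TR, so each VASO volume is paired with
#' the concurrent BOLD volume (the first of its pair).
#'
#' @param vaso voxels x nVolumes matrix (or vector) of VASO signal.
#' @param bold voxels x (2*nVolumes) matrix at the BOLD TR, or an already
#'   aligned voxels x nVolumes matrix.
#' @param restIndex indices of rest volumes (ASL/VASO volume numbering) used
#'   to compute the per-voxel rest-mean BOLD; `NULL` uses all volumes.
#' @param boldRestMean optional per-voxel rest-mean BOLD reference; when
#'   given it overrides the computation from `restIndex`.
#' @return corrected VASO, same shape as `vaso`.
#' @export
vasoBoldCorrect <- function(vaso, bold, restIndex = NULL,
                            boldRestMean = NULL) {
  vecIn <- is.null(dim(vaso))
  vaso <- rbind(vaso)[, , drop = FALSE]
  bold <- rbind(bold)[, , drop = FALSE]
  nVol <- ncol(vaso)
  if (ncol(bold) == 2L * nVol) {
    boldAligned <- bold[, 2L * seq_len(nVol) - 1L, drop = FALSE]
  } else if (ncol(bold) == nVol) {
    boldAligned <- bold
  } else {
    stop(sprintf("misaligned series: %d VASO volumes vs %d BOLD volumes",
                 nVol, ncol(bold)), call. = FALSE)
  }
  stopIfNot(all(boldAligned > 0), "BOLD signal must be positive")
  restMean <- if (!is.null(boldRestMean)) {
    rep_len(boldRestMean, nrow(vaso))
  } else {
    idx <- if (is.null(restIndex)) seq_len(nVol) else restIndex
    rowMeans(boldAligned[, idx, drop = FALSE])
  }
  out <- vaso / (boldAligned / restMean)
  if (vecIn) unname(drop(out)) else out
}

#' Convert a VASO signal ratio to a CBV ratio and percent change
#'
#' VASO signal is proportional to (1 - CBV), so the task/rest VASO ratio
#' maps to the CBV task/rest ratio as
#' \deqn{r_{CBV} = \frac{1 - r_{VASO}(1 - CBV_{rest})}{CBV_{rest}}}
#' and the percent change is `(ratio - 1) * 100`. A 2% VASO decrease at
#' baseline CBV 0.055 ml/ml corresponds to about +34.4% CBV.
#'
#' @param vasoRatio VASO task/rest signal ratio (vectorized).
#' @param cbvRest baseline CBV, ml/ml.
#' @return list with elements `ratio` and `percentChange`.
#' @examples
#' cbvRatio(0.98)$percentChange  # ~34.4
#' @export
cbvRatio <- function(vasoRatio, cbvRest = 0.055) {
  stopIfNot(cbvRest > 0 && cbvRest < 1, "cbvRest must lie in (0, 1)")
  ratio <- (1 - vasoRatio * (1 - cbvRest)) / cbvRest
  if (any(ratio <= 0) || any(ratio * cbvRest >= 1))
    stop("VASO ratio implies a CBV outside (0, 1): out of physical range",
         call. = FALSE)
  list(ratio = ratio, percentChange = (ratio - 1) * 100)
}

#' Task-minus-rest response maps
#'
#' @param taskMap task-condition map (vector/matrix).
#' @param restMap rest-condition map, same shape.
#' @return list with `delta = task - rest` and
#'   `percent = (task/rest - 1) * 100`.
#' @export
taskResponse <- function(taskMap, restMap) {
  stopIfNot(length(taskMap) == length(restMap),
            "task and rest maps must have the same shape")
  if (any(restMap == 0))
    stop("zero rest value: percent change undefined", call. = FALSE)
  list(delta = taskMap - restMap, percent = (taskMap / restMap - 1) * 100)
}

#' Average a voxel matrix within layers
#'
#' @param mat voxels x time matrix (or per-voxel vector).
#' @param labels integer layer label per voxel.
#' @return nLayers x time matrix (or per-layer vector).
#' @export
layerMeans <- function(mat, labels) {
  if (is.null(dim(mat))) {
    return(as.numeric(tapply(mat, labels, mean)))
  }
  out <- rowsum(mat, labels) / as.vector(table(labels))
  out[order(as.integer(rownames(out))), , drop = FALSE]
}

#' Condition means of a volume series
#'
#' Averages a voxels x volumes series over the volumes belonging to one
#' condition, optionally excluding transition volumes immediately after each
#' block boundary (the hemodynamic state may be mixed there).
#'
#' @param series voxels x nVolumes matrix (or vector).
#' @param volumes per-volume metadata (data.frame with `condition` and
#'   `run`), e.g. `volumeInfo(run)`.
#' @param condition condition label to average.
#' @param dropTransition number of volumes to drop after each change of
#'   condition within a run (default 1 — but note the synthetic generator
#'   switches state instantaneously, so 0 is exact there).
#' @return per-voxel mean (vector), or scalar for vector input.
#' @export
conditionMeans <- function(series, volumes, condition, dropTransition = 1) {
  keep <- volumes$condition == condition
  if (dropTransition > 0) {
    changed <- c(TRUE, volumes$condition[-1] !=
                   volumes$condition[-nrow(volumes)]) |
      c(TRUE, volumes$run[-1] != volumes$run[-nrow(volumes)])
    drop <- rep(FALSE, nrow(volumes))
    idx <- which(changed)
    for (k in seq_len(dropTransition))
      drop[pmin(idx + k - 1L, nrow(volumes))] <- TRUE
    keep <- keep & !drop
  }
  if (!any(keep))
    stop(sprintf("no volumes left for condition '%s'", condition),
         call. = FALSE)
  if (is.null(dim(series))) return(mean(series[keep]))
  rowMeans(series[, keep, drop = FALSE])
}

#' Assemble co-sampled calibration inputs from a breath-hold run
#'
#' Runs the quantification front-end of the calibration: pairwise ASL
#' subtraction and one-compartment CBF, BOLD correction of VASO (normalized
#' to the rest-mean BOLD), and pairing of a BOLD volume with each ASL/VASO
#' volume — then averages voxels within layers. The result is one co-sampled
#' (CBF, VASO, BOLD) triple per ASL/VASO volume per layer, ready for
#' [fitBreathHoldCalibration()].
#'
#' The acquisition provides two BOLD volumes per ASL/VASO volume. The VASO
#' correction uses the second volume of each pair while the calibration BOLD
#' series keeps the first: if one volume served both purposes, its noise
#' would enter the corrected-VASO regressor anticorrelated with the fit's
#' dependent variable, and the calibration would absorb noise into the
#' parameters (biasing beta upward). With distinct volumes the two noise
#' streams are independent; the physiological state within a pair is shared.
#'
#' @param run a [MultiContrastRun-class] from [simulateBreathHoldRun()] or
#'   [readMultiContrastRun()].
#' @param k constants from [quantConstants()].
#' @return list with nLayers x nVolumes matrices `cbf`, `vaso`, `bold`, and
#'   the `volumes` metadata.
#' @export
breathHoldInputs <- function(run, k = quantConstants(run@acquisition)) {
  labels <- run@layerLabels
  nVol <- ncol(run@vaso)
  perf <- pairwiseSubtract(run@asl)
  cbf <- cbfOneCompartment(perf, k)
  restIdx <- which(run@volumes$condition == "rest")
  boldForVaso <- run@bold[, 2L * seq_len(nVol), drop = FALSE]
  vasoC <- vasoBoldCorrect(run@vaso, boldForVaso,
                           restIndex = if (length(restIdx)) restIdx else NULL)
  boldAligned <- run@bold[, 2L * seq_len(nVol) - 1L, drop = FALSE]
  list(
    cbf = layerMeans(cbf, labels),
    vaso = layerMeans(vasoC, labels),
    bold = layerMeans(boldAligned, labels),
    volumes = run@volumes
  )
}

#' Layerwise task/rest quantification of a run
#'
#' Full quantification chain for a block-design run: CBF from pairwise ASL
#' subtraction and the one-compartment model, CBV from BOLD-corrected VASO
#' through the VASO-to-CBV conversion, and percent BOLD change — all as
#' condition means per layer.
#'
#' @param run a [MultiContrastRun-class].
#' @param taskCondition label of the active condition (`"task"` or `"bh"`).
#' @param k constants from [quantConstants()].
#' @param dropTransition transition volumes to exclude after each block
#'   boundary (see [conditionMeans()]).
#' @return data.frame with one row per layer: `layer`, `depth`, `cbfRest`,
#'   `cbfTask`, `cbfPercent`, `cbvRatio`, `cbvPercent`, `boldPercent`.
#' @examples
#' phys <- makePhysiology(8, "bh_default")
#' run <- simulateBreathHoldRun(phys, paradigm = bhParadigm("plateau"),
#'                              noiseSd = c(0, 0, 0), seed = 1)
#' quantifyRun(run, taskCondition = "bh", dropTransition = 0)
#' @export
quantifyRun <- function(run, taskCondition = "task",
                        k = quantConstants(run@acquisition),
                        dropTransition = 1) {
  labels <- run@layerLabels
  inp <- breathHoldInputs(run, k)
  vol <- inp$volumes

  cbfRest <- conditionMeans(inp$cbf, vol, "rest", dropTransition)
  cbfTask <- conditionMeans(inp$cbf, vol, taskCondition, dropTransition)
  vasoRest <- conditionMeans(inp$vaso, vol, "rest", dropTransition)
  vasoTask <- conditionMeans(inp$vaso, vol, taskCondition, dropTransition)
  boldRest <- conditionMeans(inp$bold, vol, "rest", dropTransition)
  boldTask <- conditionMeans(inp$bold, vol, taskCondition, dropTransition)

  cbfResp <- taskResponse(cbfTask, cbfRest)
  cbv <- cbvRatio(vasoTask / vasoRest, k$cbvRest)
  nL <- max(labels)
  data.frame(
    layer = seq_len(nL),
    depth = layerDepths(nL),
    cbfRest = cbfRest,
    cbfTask = cbfTask,
    cbfPercent = cbfResp$percent,
    cbvRatio = cbv$ratio,
    cbvPercent = cbv$percentChange,
    boldPercent = boldChange(boldTask, boldRest)
  )
}

#' Layerwise CMRO2 ratios for a task run
#'
#' Combines the quantified CBF/CBV/BOLD responses of a task run with fitted
#' Davis parameters (per layer) to invert the Davis model for the CMRO2
#' task/rest ratio per layer.
#'
#' @param quant data.frame from [quantifyRun()].
#' @param m,beta Davis parameters, scalars or per-layer vectors (e.g. from
#'   per-layer [CalibrationFit-class] objects).
#' @return the `quant` data.frame with added columns `cmro2Ratio` and
#'   `cmro2Percent`.
#' @export
cmro2Profile <- function(quant, m, beta) {
  r <- cmro2Ratio(quant$boldPercent / 100,
                  rCbf = 1 + quant$cbfPercent / 100,
                  rCbv = quant$cbvRatio, m = m, beta = beta)
  quant$cmro2Ratio <- r
  quant$cmro2Percent <- (r - 1) * 100
  quant
}
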