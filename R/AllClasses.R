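#' @import methods
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))

#' Acquisition configuration for the multi-contrast sequence
#'
#' Holds the pulse-sequence timing and labeling constants shared by the
#' synthetic generator and the CBF quantification: pCASL labeling duration and
#' post-labeling delay, arterial blood T1 and T2, blood-brain partition
#' coefficient, labeling and background-suppression efficiencies, and the
#' volume TRs of the interleaved readout (24 s per ASL/VASO volume, 12 s per
#' BOLD volume).
#'
#' @slot labelingDuration pCASL labeling duration in seconds.
#' @slot postLabelingDelay post-labeling delay (PLD) in seconds.
#' @slot t1Blood arterial blood T1 in seconds.
#' @slot lambdaPartition tissue-to-blood partition coefficient (ml/g).
#' @slot labelingEfficiency pCASL labeling efficiency, in (0, 1].
#' @slot bsInversionEfficiency background-suppression inversion efficiency.
#' @slot t2Arterial arterial blood T2 in seconds (drives slice-deblurring).
#' @slot volumeTrAslVaso volume TR of one ASL/VASO image in seconds.
#' @slot volumeTrBold volume TR of one BOLD image in seconds.
#' @slot echoTime echo time in seconds.
#' @slot nSlices number of slices in the 3D readout.
#'
#' @seealso [acquisitionConfig()]
#' @export
setClass("AcquisitionConfig",
  representation(
    labelingDuration = "numeric",
    postLabelingDelay = "numeric",
    t1Blood = "numeric",
    lambdaPartition = "numeric",
    labelingEfficiency = "numeric",
    bsInversionEfficiency = "numeric",
    t2Arterial = "numeric",
    volumeTrAslVaso = "numeric",
    volumeTrBold = "numeric",
    echoTime = "numeric",
    nSlices = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  num <- c(
    labelingDuration = object@labelingDuration,
    postLabelingDelay = object@postLabelingDelay,
    t1Blood = object@t1Blood,
    lambdaPartition = object@lambdaPartition,
    labelingEfficiency = object@labelingEfficiency,
    bsInversionEfficiency = object@bsInversionEfficiency,
    t2Arterial = object@t2Arterial,
    volumeTrAslVaso = object@volumeTrAslVaso,
    volumeTrBold = object@volumeTrBold,
    echoTime = object@echoTime,
    nSlices = object@nSlices
  )
  if (any(!is.finite(num)) || any(num <= 0))
    msg <- c(msg, "all acquisition parameters must be finite and positive")
  if (object@labelingEfficiency > 1 || object@bsInversionEfficiency > 1)
    msg <- c(msg, "efficiencies must lie in (0, 1]")
  if (length(msg) == 0 &&
      object@postLabelingDelay + object@labelingDuration >= object@volumeTrBold)
    msg <- c(msg, "labeling duration + PLD must fit within one BOLD volume TR")
  if (length(msg)) msg else TRUE
})

#' Layer-resolved ground-truth physiology
#'
#' Baseline perfusion and blood volume per cortical layer together with the
#' Davis-model parameters and task/breath-hold response ratios used by the
#' forward generator (and recovered by the analysis chain in tests). All
#' responses are task/rest ratios; reported percent changes are
#' (ratio - 1) * 100.
#'
#' @slot nLayers number of cortical layers (depth samples).
#' @slot baselineCbf baseline CBF per layer, ml/100g/min.
#' @slot baselineCbv baseline CBV per layer, ml/ml.
#' @slot davisM Davis-model M (maximal BOLD change, fraction) per layer.
#' @slot davisBeta Davis-model beta per layer.
#' @slot cbfResponse CBF task/rest ratio per layer for the active condition.
#' @slot cbvResponse CBV task/rest ratio per layer, or `NULL` to derive it
#'   from `cbfResponse` through Grubb's power law.
#' @slot cmro2Response CMRO2 task/rest ratio per layer.
#' @slot grubbAlpha Grubb exponent coupling CBV to CBF when `cbvResponse`
#'   is not given explicitly.
#' @slot scenario name of the generating scenario.
#'
#' @seealso [makePhysiology()]
#' @export
setClass("LayerPhysiology",
  representation(
    nLayers = "integer",
    baselineCbf = "numeric",
    baselineCbv = "numeric",
    davisM = "numeric",
    davisBeta = "numeric",
    cbfResponse = "numeric",
    cbvResponse = "ANY",
    cmro2Response = "numeric",
    grubbAlpha = "numeric",
    scenario = "character"
  )
)

setValidity("LayerPhysiology", function(object) {
  n <- object@nLayers
  msg <- character()
  if (n < 2L) msg <- c(msg, "nLayers must be >= 2")
  lens <- c(
    length(object@baselineCbf), length(object@baselineCbv),
    length(object@davisM), length(object@davisBeta),
    length(object@cbfResponse), length(object@cmro2Response)
  )
  if (any(lens != n))
    msg <- c(msg, "all per-layer vectors must have length nLayers")
  if (!is.null(object@cbvResponse)) {
    if (!is.numeric(object@cbvResponse) || length(object@cbvResponse) != n)
      msg <- c(msg, "cbvResponse must be NULL or a numeric of length nLayers")
    else if (any(object@cbvResponse <= 0))
      msg <- c(msg, "response ratios must be positive")
  }
  if (any(object@cbfResponse <= 0) || any(object@cmro2Response <= 0))
    msg <- c(msg, "response ratios must be positive")
  if (any(object@baselineCbv <= 0) || any(object@baselineCbv >= 1))
    msg <- c(msg, "baselineCbv must lie in (0, 1)")
  if (any(object@davisM < 0)) msg <- c(msg, "davisM must be >= 0")
  if (any(object@davisBeta <= 0)) msg <- c(msg, "davisBeta must be > 0")
  if (any(object@baselineCbf <= 0)) msg <- c(msg, "baselineCbf must be > 0")
  if (length(msg)) msg else TRUE
})

#' Block paradigm specification
#'
#' Describes an interleaved rest/active block design: a finger-tapping style
#' task paradigm or a breath-hold (BH) hypercapnia paradigm. Durations are in
#' seconds and must be integer multiples of the ASL/VASO volume TR so that
#' every volume falls entirely within one block.
#'
#' @slot blockType `"task_block"` or `"breath_hold"`.
#' @slot onDuration duration of the active (task/BH) block, seconds.
#' @slot offDuration duration of the rest block, seconds.
#' @slot nCycles number of rest+active cycles.
#' @slot leadIn initial rest baseline before the first cycle, seconds.
#' @slot hypercapniaProfile `"ramped"` (linear ramp to a jittered per-cycle
#'   peak with exponential inter-block recovery) or `"plateau"` (full-depth
#'   square wave); breath-hold only.
#' @slot responseDelay physiological onset delay relative to the cue, seconds.
#'
#' @seealso [paradigmSpec()], [bhParadigm()], [taskParadigm()]
#' @export
setClass("ParadigmSpec",
  representation(
    blockType = "character",
    onDuration = "numeric",
    offDuration = "numeric",
    nCycles = "integer",
    leadIn = "numeric",
    hypercapniaProfile = "character",
    responseDelay = "numeric"
  )
)

setValidity("ParadigmSpec", function(object) {
  msg <- character()
  if (!object@blockType %in% c("task_block", "breath_hold"))
    msg <- c(msg, "blockType must be 'task_block' or 'breath_hold'")
  if (object@onDuration <= 0 || object@offDuration <= 0)
    msg <- c(msg, "block durations must be positive")
  if (object@nCycles < 1L) msg <- c(msg, "nCycles must be >= 1")
  if (object@leadIn < 0) msg <- c(msg, "leadIn must be >= 0")
  if (!object@hypercapniaProfile %in% c("ramped", "plateau"))
    msg <- c(msg, "hypercapniaProfile must be 'ramped' or 'plateau'")
  if (length(msg)) msg else TRUE
})

#' A multi-contrast acquisition (ASL + VASO + BOLD)
#'
#' Container for one or more runs of the interleaved multi-contrast
#' acquisition. ASL is stored as interleaved control/label volumes (two time
#' points per ASL/VASO volume TR, normalized to M0); VASO has one volume per
#' ASL/VASO TR; BOLD has two volumes per ASL/VASO TR (volume TR 12 s vs 24 s).
#' `volumes` and `volumesBold` carry per-volume metadata (run, onset,
#' condition, hypercapnia level, outlier flags).
#'
#' @slot asl voxels x (2 * nVolumes) matrix, interleaved control/label.
#' @slot vaso voxels x nVolumes matrix.
#' @slot bold voxels x (2 * nVolumes) matrix.
#' @slot volumes data.frame with one row per ASL/VASO volume: `run`,
#'   `volume`, `onset`, `condition`, `h` (hypercapnia level in \[0,1\]),
#'   `outlier`.
#' @slot volumesBold data.frame with one row per BOLD volume (same columns).
#' @slot layerLabels integer layer index (1..nLayers) per voxel.
#' @slot m0 proton-density scaling per voxel (signals are stored in M0 units).
#' @slot acquisition the [AcquisitionConfig-class] used.
#' @slot truth optional [LayerPhysiology-class] ground truth (synthetic runs).
#' @slot meta free-form list (drift slopes, noise SDs, injected outliers).
#'
#' @seealso [simulateBreathHoldRun()], [simulateTaskRun()]
#' @export
setClass("MultiContrastRun",
  representation(
    asl = "matrix",
    vaso = "matrix",
    bold = "matrix",
    volumes = "data.frame",
    volumesBold = "data.frame",
    layerLabels = "integer",
    m0 = "numeric",
    acquisition = "AcquisitionConfig",
    truth = "ANY",
    meta = "list"
  )
)

setValidity("MultiContrastRun", function(object) {
  msg <- character()
  nVox <- nrow(object@vaso)
  nVol <- ncol(object@vaso)
  if (ncol(object@asl) %% 2L != 0L)
    msg <- c(msg, "ASL series must have an even number of time points")
  if (ncol(object@asl) != 2L * nVol)
    msg <- c(msg, "ASL must hold one control/label pair per ASL/VASO volume")
  if (ncol(object@bold) != 2L * nVol)
    msg <- c(msg, "BOLD must hold two volumes per ASL/VASO volume")
  if (nrow(object@asl) != nVox || nrow(object@bold) != nVox)
    msg <- c(msg, "all contrasts must share the voxel dimension")
  if (length(object@layerLabels) != nVox || length(object@m0) != nVox)
    msg <- c(msg, "layerLabels and m0 must have one entry per voxel")
  if (nrow(object@volumes) != nVol)
    msg <- c(msg, "volumes metadata must have one row per ASL/VASO volume")
  if (nrow(object@volumesBold) != 2L * nVol)
    msg <- c(msg, "volumesBold metadata must have one row per BOLD volume")
  if (!all(is.finite(object@asl)) || !all(is.finite(object@vaso)) ||
      !all(is.finite(object@bold)))
    msg <- c(msg, "all series must be finite")
  lay <- object@layerLabels
  if (length(lay) && !all(seq_len(max(lay)) %in% unique(lay)))
    msg <- c(msg, "layer labels must cover 1..nLayers")
  if (length(msg)) msg else TRUE
})

#' Result of the joint five-unknown breath-hold calibration
#'
#' Fitted Davis-model parameters M and beta together with the three baseline
#' signals (CBF, BOLD-corrected VASO, BOLD) estimated simultaneously from all
#' rest and breath-hold time points, with residual diagnostics.
#'
#' @slot m fitted M (maximal BOLD change, fraction).
#' @slot beta fitted Davis exponent.
#' @slot baselineCbf fitted baseline CBF, ml/100g/min.
#' @slot baselineVaso fitted baseline (BOLD-corrected) VASO signal.
#' @slot baselineBold fitted baseline BOLD signal.
#' @slot rmse root-mean-square residual on the BOLD signal.
#' @slot converged logical convergence flag from the optimizer.
#' @slot nPoints number of co-sampled time points used.
#' @slot cbvRest baseline CBV (ml/ml) assumed in the VASO-to-CBV conversion.
#'
#' @seealso [fitBreathHoldCalibration()]
#' @export
setClass("CalibrationFit",
  representation(
    m = "numeric",
    beta = "numeric",
    baselineCbf = "numeric",
    baselineVaso = "numeric",
    baselineBold = "numeric",
    rmse = "numeric",
    converged = "logical",
    nPoints = "integer",
    cbvRest = "numeric"
  )
)

setValidity("CalibrationFit", function(object) {
  msg <- character()
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (object@nPoints <= 5L)
    msg <- c(msg, "nPoints must exceed the number of unknowns (5)")
  if (length(msg)) msg else TRUE
})

#' Depth-ordered laminar response profile
#'
#' Mean response and standard error as a function of normalized cortical
#' depth (0 = white-matter boundary, 1 = CSF boundary). Profiles feed the
#' two-peak statistic and the group comparisons.
#'
#' @slot depth normalized depth per sample, strictly increasing in (0, 1).
#' @slot mean mean response per depth sample.
#' @slot se standard error per depth sample.
#' @slot n number of observations (voxels or subjects) per depth sample.
#'
#' @seealso [buildProfile()], [twoPeakTest()]
#' @export
setClass("LaminarProfile",
  representation(
    depth = "numeric",
    mean = "numeric",
    se = "numeric",
    n = "integer"
  )
)

setValidity("LaminarProfile", function(object) {
  msg <- character()
  k <- length(object@depth)
  if (length(object@mean) != k || length(object@se) != k ||
      length(object@n) != k)
    msg <- c(msg, "depth, mean, se and n must share one length")
  if (k >= 2 && any(diff(object@depth) <= 0))
    msg <- c(msg, "depth must be strictly increasing")
  if (any(object@se < 0)) msg <- c(msg, "se must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Two-peak bootstrap test result
#'
#' Adjusted R-squared of the single- and double-Gaussian fits to a laminar
#' profile, their difference (the two-peak score), and the bootstrap p-value:
#' the probability that a score at least as large arises from the best
#' single-peak curve plus per-depth noise alone.
#'
#' @slot r2AdjSingle adjusted R-squared of the single-Gaussian fit.
#' @slot r2AdjDouble adjusted R-squared of the double-Gaussian fit.
#' @slot r2Diff difference double - single.
#' @slot pValue bootstrap p-value.
#' @slot nBoot number of bootstrap draws.
#'
#' @seealso [twoPeakTest()]
#' @export
setClass("TwoPeakResult",
  representation(
    r2AdjSingle = "numeric",
    r2AdjDouble = "numeric",
    r2Diff = "numeric",
    pValue = "numeric",
    nBoot = "integer"
  )
)

setValidity("TwoPeakResult", function(object) {
  msg <- character()
  if (abs(object@r2Diff - (object@r2AdjDouble - object@r2AdjSingle)) > 1e-8)
    msg <- c(msg, "r2Diff must equal r2AdjDouble - r2AdjSingle")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
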