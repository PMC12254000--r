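#' @title Accessors for layercal classes
#' @description Small accessor generics so that user code never touches slots
#'   directly: layer labels, per-volume metadata, number of layers, and the
#'   contrast matrices of a [MultiContrastRun-class].
#' @param object a layercal S4 object.
#' @param contrast one of `"asl"`, `"vaso"`, `"bold"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))

#' @rdname accessors
#' @export
setMethod("nLayers", "LayerPhysiology", function(object) object@nLayers)

#' @rdname accessors
#' @export
setMethod("nLayers", "MultiContrastRun", function(object)
  max(object@layerLabels))

#' @rdname accessors
#' @export
setGeneric("layerLabels", function(object) standardGeneric("layerLabels"))

#' @rdname accessors
#' @export
setMethod("layerLabels", "MultiContrastRun", function(object)
  object@layerLabels)

#' @rdname accessors
#' @export
setGeneric("volumeInfo", function(object, contrast = "vaso")
  standardGeneric("volumeInfo"))

#' @rdname accessors
#' @export
setMethod("volumeInfo", "MultiContrastRun", function(object,
                                                     contrast = "vaso") {
  if (identical(contrast, "bold")) object@volumesBold else object@volumes
})

#' @rdname accessors
#' @export
setGeneric("contrastSeries", function(object, contrast)
  standardGeneric("contrastSeries"))

#' @rdname accessors
#' @export
setMethod("contrastSeries", "MultiContrastRun", function(object, contrast) {
  switch(match.arg(contrast, c("asl", "vaso", "bold")),
    asl = object@asl, vaso = object@vaso, bold = object@bold)
})

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("groundTruth", "MultiContrastRun", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("davisParams", function(object) standardGeneric("davisParams"))

#' @rdname accessors
#' @export
setMethod("davisParams", "CalibrationFit", function(object)
  c(m = object@m, beta = object@beta))

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig\n")
  cat(sprintf("  labeling %.0f ms, PLD %.0f ms, T1b %.2f s, T2a %.0f ms\n",
              1000 * object@labelingDuration, 1000 * object@postLabelingDelay,
              object@t1Blood, 1000 * object@t2Arterial))
  cat(sprintf("  efficiencies: label %.1f%%, BS %.1f%%; lambda %.2f ml/g\n",
              100 * object@labelingEfficiency,
              100 * object@bsInversionEfficiency, object@lambdaPartition))
  cat(sprintf("  volume TR: ASL/VASO %g s, BOLD %g s; TE %.1f ms; %d slices\n",
              object@volumeTrAslVaso, object@volumeTrBold,
              1000 * object@echoTime, as.integer(object@nSlices)))
})

setMethod("show", "LayerPhysiology", function(object) {
  cat(sprintf("LayerPhysiology: %d layers, scenario '%s'\n",
              object@nLayers, object@scenario))
  cat(sprintf("  baseline CBF %.1f-%.1f ml/100g/min, CBV %.3f-%.3f ml/ml\n",
              min(object@baselineCbf), max(object@baselineCbf),
              min(object@baselineCbv), max(object@baselineCbv)))
  cat(sprintf("  M %.3f-%.3f, beta %.2f-%.2f; CBF response %.2f-%.2f\n",
              min(object@davisM), max(object@davisM),
              min(object@davisBeta), max(object@davisBeta),
              min(object@cbfResponse), max(object@cbfResponse)))
  if (is.null(object@cbvResponse))
    cat(sprintf("  CBV response: Grubb-coupled, alpha = %.2f\n",
                object@grubbAlpha))
})

setMethod("show", "ParadigmSpec", function(object) {
  cat(sprintf("ParadigmSpec: %s, %d cycles of %g s off / %g s on",
              object@blockType, object@nCycles, object@offDuration,
              object@onDuration))
  if (object@leadIn > 0) cat(sprintf(", %g s lead-in", object@leadIn))
  cat("\n")
  if (object@blockType == "breath_hold")
    cat(sprintf("  hypercapnia profile: %s\n", object@hypercapniaProfile))
})

setMethod("show", "MultiContrastRun", function(object) {
  nVol <- ncol(object@vaso)
  cat(sprintf(
    "MultiContrastRun: %d voxels, %d layers, %d ASL/VASO volumes (%d runs)\n",
    nrow(object@vaso), nLayers(object), nVol,
    length(unique(object@volumes$run))))
  cat(sprintf("  ASL %d interleaved control/label points, BOLD %d volumes\n",
              ncol(object@asl), ncol(object@bold)))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(object@volumes$condition)),
                            table(object@volumes$condition)),
                    collapse = ", ")))
  if (!is.null(object@truth)) cat("  ground truth attached\n")
})

setMethod("show", "CalibrationFit", function(object) {
  cat("CalibrationFit (joint 5-unknown breath-hold fit)\n")
  cat(sprintf("  M = %.4f (%.2f%%), beta = %.3f\n",
              object@m, 100 * object@m, object@beta))
  cat(sprintf("  baselines: CBF %.1f ml/100g/min, VASO %.4f, BOLD %.4f\n",
              object@baselineCbf, object@baselineVaso, object@baselineBold))
  cat(sprintf("  rmse %.3g over %d points; converged: %s\n",
              object@rmse, object@nPoints, object@converged))
})

setMethod("show", "LaminarProfile", function(object) {
  cat(sprintf("LaminarProfile: %d depth samples in [%.2f, %.2f]\n",
              length(object@depth), min(object@depth), max(object@depth)))
  cat(sprintf("  mean range [%.3g, %.3g], median se %.3g\n",
              min(object@mean), max(object@mean), stats::median(object@se)))
})

setMethod("show", "TwoPeakResult", function(object) {
  cat(sprintf(
    "TwoPeakResult: R2_diff = %.3f (single %.3f, double %.3f), p = %.4g (%d draws)\n",
    object@r2Diff, object@r2AdjSingle, object@r2AdjDouble, object@pValue,
    object@nBoot))
})

#' Convert a LaminarProfile to a data.frame
#'
#' @param x a [LaminarProfile-class].
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return a data.frame with columns `depth`, `mean`, `se`, `n`.
#' @export
as.data.frame.LaminarProfile <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(depth = x@depth, mean = x@mean, se = x@se, n = x@n)
}
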