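#' Construct an acquisition configuration
#'
#' Defaults reproduce the 7T zoomed-GRASE multi-contrast protocol: 1280 ms
#' pCASL labeling, 1160 ms post-labeling delay, arterial blood T1 of 2.1 s,
#' partition coefficient 0.9 ml/g, 82.1% labeling efficiency, 95%
#' background-suppression inversion efficiency, arterial T2 of 68 ms, 24 s
#' volume TR for ASL/VASO and 12 s for BOLD, TE 17.2 ms, 14 slices.
#'
#' @param labelingDuration pCASL labeling duration, seconds.
#' @param postLabelingDelay post-labeling delay, seconds.
#' @param t1Blood arterial blood T1, seconds.
#' @param lambdaPartition tissue-to-blood partition coefficient, ml/g.
#' @param labelingEfficiency labeling efficiency, fraction in (0, 1].
#' @param bsInversionEfficiency background-suppression inversion efficiency.
#' @param t2Arterial arterial blood T2 at 7T, seconds.
#' @param volumeTrAslVaso ASL/VASO volume TR, seconds.
#' @param volumeTrBold BOLD volume TR, seconds.
#' @param echoTime echo time, seconds.
#' @param nSlices number of slices.
#'
#' @return an [AcquisitionConfig-class] object.
#' @examples
#' acq <- acquisitionConfig()
#' acq
#' @export
acquisitionConfig <- function(labelingDuration = 1.280,
                              postLabelingDelay = 1.160,
                              t1Blood = 2.1,
                              lambdaPartition = 0.9,
                              labelingEfficiency = 0.821,
                              bsInversionEfficiency = 0.95,
                              t2Arterial = 0.068,
                              volumeTrAslVaso = 24,
                              volumeTrBold = 12,
                              echoTime = 0.0172,
                              nSlices = 14) {
  new("AcquisitionConfig",
    labelingDuration = labelingDuration,
    postLabelingDelay = postLabelingDelay,
    t1Blood = t1Blood,
    lambdaPartition = lambdaPartition,
    labelingEfficiency = labelingEfficiency,
    bsInversionEfficiency = bsInversionEfficiency,
    t2Arterial = t2Arterial,
    volumeTrAslVaso = volumeTrAslVaso,
    volumeTrBold = volumeTrBold,
    echoTime = echoTime,
    nSlices = nSlices
  )
}

#' Quantification constants for the one-compartment CBF model
#'
#' Bundles the labeling constants needed by [cbfOneCompartment()] and the
#' baseline CBV assumed by the VASO-to-CBV conversion (0.055 ml/ml by
#' default) into a plain named list.
#'
#' @param acq an [AcquisitionConfig-class]; its labeling fields are copied.
#' @param cbvRest baseline CBV in ml/ml.
#' @return a named list with elements `lambdaPartition`, `t1Blood`,
#'   `labelingEfficiency`, `bsInversionEfficiency`, `labelingDuration`,
#'   `postLabelingDelay`, `cbvRest`.
#' @examples
#' k <- quantConstants()
#' k$cbvRest
#' @export
quantConstants <- function(acq = acquisitionConfig(), cbvRest = 0.055) {
  stopIfNot(cbvRest > 0 && cbvRest < 1, "cbvRest must lie in (0, 1)")
  list(
    lambdaPartition = acq@lambdaPartition,
    t1Blood = acq@t1Blood,
    labelingEfficiency = acq@labelingEfficiency,
    bsInversionEfficiency = acq@bsInversionEfficiency,
    labelingDuration = acq@labelingDuration,
    postLabelingDelay = acq@postLabelingDelay,
    cbvRest = cbvRest
  )
}
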