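#' Construct layer physiology explicitly
#'
#' Low-level constructor for [LayerPhysiology-class]; scalar arguments are
#' recycled across layers. Most users will call [makePhysiology()] for one of
#' the named scenarios.
#'
#' @param nLayers number of layers (>= 2).
#' @param baselineCbf baseline CBF per layer, ml/100g/min.
#' @param baselineCbv baseline CBV per layer, ml/ml.
#' @param davisM Davis M per layer (fraction).
#' @param davisBeta Davis beta per layer.
#' @param cbfResponse CBF task/rest ratio per layer.
#' @param cbvResponse CBV task/rest ratio per layer, or `NULL` for Grubb
#'   coupling `cbvResponse = cbfResponse^grubbAlpha`.
#' @param cmro2Response CMRO2 task/rest ratio per layer.
#' @param grubbAlpha Grubb exponent used when `cbvResponse` is `NULL`.
#' @param scenario scenario label stored with the object.
#' @return a [LayerPhysiology-class].
#' @export
layerPhysiology <- function(nLayers,
                            baselineCbf = 55,
                            baselineCbv = 0.055,
                            davisM = 0.055,
                            davisBeta = 1.10,
                            cbfResponse = 1,
                            cbvResponse = NULL,
                            cmro2Response = 1,
                            grubbAlpha = 0.38,
                            scenario = "custom") {
  n <- as.integer(nLayers)
  rec <- function(x) rep_len(as.numeric(x), n)
  new("LayerPhysiology",
    nLayers = n,
    baselineCbf = rec(baselineCbf),
    baselineCbv = rec(baselineCbv),
    davisM = rec(davisM),
    davisBeta = rec(davisBeta),
    cbfResponse = rec(cbfResponse),
    cbvResponse = if (is.null(cbvResponse)) NULL else rec(cbvResponse),
    cmro2Response = rec(cmro2Response),
    grubbAlpha = grubbAlpha,
    scenario = scenario
  )
}

#' Normalized depth of layer centers
#'
#' Layer i of n spans ((i-1)/n, i/n) in normalized cortical depth; its center
#' is (i - 0.5)/n, with 0 at the white-matter and 1 at the CSF boundary.
#'
#' @param nLayers number of layers.
#' @return numeric vector of layer-center depths.
#' @export
layerDepths <- function(nLayers) (seq_len(nLayers) - 0.5) / nLayers

#' Make ground-truth layer physiology for a named scenario
#'
#' Builds the layerwise baselines, Davis parameters and response ratios used
#' by the forward generator:
#'
#' * `"flat"` — one shared baseline everywhere and unit response ratios; the
#'   identity scenario for null tests.
#' * `"bh_default"` — breath-hold hypercapnia: CBF response peaking in the
#'   deep layers (45% at the deepest, falling to 32% superficially), CBV
#'   response peaking superficially (19%, from 14% at depth), CMRO2
#'   unchanged; M ramps up from deep layers to a 5.5% plateau from
#'   mid-to-superficial depth; beta increases monotonically from 0.97 (deep)
#'   to 1.22 (superficial).
#' * `"task_two_peak"` — finger-tapping style activation with two response
#'   peaks across depth (motor output in deep layers, sensory/premotor input
#'   superficially): CBF peaks of +126% (deep) and +111% (superficial), CBV
#'   peaks of +28% and +46%, CMRO2 coupled at 40% of the CBF response
#'   amplitude. Peak centers are aligned to layer centers at roughly 0.2 and
#'   0.8 normalized depth.
#' * `"custom"` — defaults of [layerPhysiology()]; pass overrides there.
#'
#' Baseline CBF rises from 45 (deep) to 65 (superficial) ml/100g/min in the
#' non-flat scenarios, reflecting the lower resting perfusion of deep layers;
#' baseline CBV is 0.055 ml/ml everywhere.
#'
#' @param nLayers number of layers (>= 2); 15 for a motor-cortex style
#'   profile, 8 for a visual-cortex style profile.
#' @param scenario one of `"flat"`, `"bh_default"`, `"task_two_peak"`,
#'   `"custom"`.
#' @return a [LayerPhysiology-class].
#' @examples
#' makePhysiology(8, "bh_default")
#' @export
makePhysiology <- function(nLayers,
                           scenario = c("flat", "bh_default",
                                        "task_two_peak", "custom")) {
  scenario <- match.arg(scenario)
  n <- as.integer(nLayers)
  stopIfNot(n >= 2L, "nLayers must be >= 2")
  d <- layerDepths(n)

  if (scenario == "flat") {
    return(layerPhysiology(n, scenario = "flat"))
  }
  if (scenario == "custom") {
    return(layerPhysiology(n, scenario = "custom"))
  }

  baselineCbf <- linSpace(45, 65, n)
  # M: ramp from 0.04 at the WM boundary to a 0.055 plateau for depth >= 0.5
  davisM <- 0.04 + (0.055 - 0.04) * pmin(d / 0.5, 1)
  davisBeta <- linSpace(0.97, 1.22, n)

  if (scenario == "bh_default") {
    return(layerPhysiology(n,
      baselineCbf = baselineCbf,
      davisM = davisM,
      davisBeta = davisBeta,
      cbfResponse = linSpace(1.45, 1.32, n),
      cbvResponse = linSpace(1.14, 1.19, n),
      cmro2Response = 1,
      scenario = "bh_default"
    ))
  }

  # task_two_peak: double-Gaussian response shape with centers aligned to
  # layer centers near 0.2 and 0.8 normalized depth, width 0.12.
  i1 <- max(2L, round(0.2 * n))
  i2 <- min(n - 1L, round(0.8 * n))
  c1 <- d[i1]; c2 <- d[i2]; w <- 0.12
  bump <- function(a1, a2)
    1 + a1 * exp(-(d - c1)^2 / (2 * w^2)) + a2 * exp(-(d - c2)^2 / (2 * w^2))
  cbf <- bump(1.26, 1.11)      # peaks +126% deep, +111% superficial
  cbv <- bump(0.28, 0.46)      # peaks +28% deep, +46% superficial
  cmro2 <- bump(0.4 * 1.26, 0.4 * 1.11)
  layerPhysiology(n,
    baselineCbf = baselineCbf,
    davisM = davisM,
    davisBeta = davisBeta,
    cbfResponse = cbf,
    cbvResponse = cbv,
    cmro2Response = cmro2,
    scenario = "task_two_peak"
  )
}
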