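#' Construct a block paradigm
#'
#' @param blockType `"task_block"` or `"breath_hold"`.
#' @param onDuration active-block duration, seconds.
#' @param offDuration rest-block duration, seconds.
#' @param nCycles number of rest+active cycles.
#' @param leadIn initial rest baseline, seconds.
#' @param hypercapniaProfile `"ramped"` or `"plateau"` (breath-hold only);
#'   see [simulateBreathHoldRun()].
#' @param responseDelay physiological onset delay vs the cue, seconds.
#' @return a [ParadigmSpec-class].
#' @export
paradigmSpec <- function(blockType, onDuration, offDuration, nCycles,
                         leadIn = 0, hypercapniaProfile = "ramped",
                         responseDelay = 0) {
  new("ParadigmSpec",
    blockType = blockType, onDuration = onDuration,
    offDuration = offDuration, nCycles = as.integer(nCycles),
    leadIn = leadIn, hypercapniaProfile = hypercapniaProfile,
    responseDelay = responseDelay
  )
}

#' Default breath-hold paradigm
#'
#' 12 cycles of interleaved 24 s rest and 24 s breath-hold, preceded by a
#' 72 s rest baseline, so that one run yields 27 ASL/VASO volumes and two
#' runs the 54 co-sampled time points of the joint calibration fit.
#'
#' @param hypercapniaProfile `"ramped"` (default) or `"plateau"`.
#' @return a [ParadigmSpec-class].
#' @export
bhParadigm <- function(hypercapniaProfile = "ramped") {
  paradigmSpec("breath_hold", onDuration = 24, offDuration = 24,
               nCycles = 12, leadIn = 72,
               hypercapniaProfile = hypercapniaProfile)
}

#' Default task paradigm
#'
#' Five cycles of interleaved 48 s rest and 48 s task (8 min per run).
#'
#' @param nCycles number of rest+task cycles.
#' @return a [ParadigmSpec-class].
#' @export
taskParadigm <- function(nCycles = 5) {
  paradigmSpec("task_block", onDuration = 48, offDuration = 48,
               nCycles = nCycles)
}

#' Forward-model the three contrasts from a physiological state
#'
#' Maps per-layer response ratios (r_CBF, r_CBV, r_CMRO2) to the noiseless
#' signals the acquisition would measure, in M0 units:
#' * `aslDiffOverM0` — the control-minus-label difference implied by the
#'   one-compartment model at CBF = baseline * r_CBF (exact inverse of
#'   [cbfOneCompartment()]);
#' * `bold` — baseline 1 times (1 + dBOLD) with dBOLD from [davisForward()];
#' * `vaso` — (1 - CBV)/(1 - CBV_rest) times the same (1 + dBOLD) factor, so
#'   that dividing VASO by BOLD removes the contamination exactly.
#'
#' @param physio a [LayerPhysiology-class].
#' @param acq an [AcquisitionConfig-class].
#' @param rCbf,rCbv,rCmro2 per-layer response ratios (> 0), recycled to
#'   `nLayers(physio)`.
#' @return list of per-layer numeric vectors `aslDiffOverM0`, `vaso`,
#'   `bold`, `deltaBold`.
#' @examples
#' phys <- makePhysiology(8, "flat")
#' forwardSignals(phys, rCbf = 1, rCbv = 1, rCmro2 = 1)$deltaBold  # zeros
#' @export
forwardSignals <- function(physio, acq = acquisitionConfig(),
                           rCbf = 1, rCbv = 1, rCmro2 = 1) {
  n <- physio@nLayers
  rCbf <- rep_len(rCbf, n); rCbv <- rep_len(rCbv, n)
  rCmro2 <- rep_len(rCmro2, n)
  stopIfNot(all(rCbf > 0) && all(rCbv > 0) && all(rCmro2 > 0),
            "state ratios must be positive")
  k <- quantConstants(acq, cbvRest = physio@baselineCbv[1])
  deltaBold <- davisForward(physio@davisM, physio@davisBeta,
                            rCbf, rCbv, rCmro2)
  cbv <- physio@baselineCbv * rCbv
  list(
    aslDiffOverM0 = physio@baselineCbf * rCbf / cbfPerUnitPerfusion(k),
    vaso = (1 - cbv) / (1 - physio@baselineCbv) * (1 + deltaBold),
    bold = 1 + deltaBold,
    deltaBold = deltaBold
  )
}

# Per-volume hypercapnia levels for one run. The continuous model: h ramps
# linearly over each breath-hold block toward a cycle-specific peak (jittered
# U(0.7, 1) for the "ramped" profile), and recovers exponentially with a
# 20 s time constant between blocks (incomplete recovery). The physiological
# state is taken as piecewise-constant per ASL/VASO volume, evaluated at the
# volume midpoint of the continuous model.
hypercapniaSchedule <- function(paradigm, trVol) {
  nOn <- paradigm@onDuration / trVol
  nOff <- paradigm@offDuration / trVol
  nLead <- paradigm@leadIn / trVol
  stopIfNot(all(abs(c(nOn, nOff, nLead) - round(c(nOn, nOff, nLead))) < 1e-9),
            "block durations must be integer multiples of the ASL/VASO TR")
  nOn <- round(nOn); nOff <- round(nOff); nLead <- round(nLead)
  onCond <- if (paradigm@blockType == "breath_hold") "bh" else "task"
  cond <- c(rep("rest", nLead),
            rep(c(rep("rest", nOff), rep(onCond, nOn)), paradigm@nCycles))
  nVol <- length(cond)
  onset <- (seq_len(nVol) - 1L) * trVol

  if (paradigm@blockType != "breath_hold") {
    h <- as.numeric(cond == onCond)
    return(data.frame(volume = seq_len(nVol), onset = onset,
                      condition = cond, h = h))
  }

  if (paradigm@hypercapniaProfile == "plateau") {
    h <- as.numeric(cond == "bh")
    return(data.frame(volume = seq_len(nVol), onset = onset,
                      condition = cond, h = h))
  }

  # ramped profile, simulated on a 1 s grid
  peaks <- stats::runif(paradigm@nCycles, 0.7, 1.0)
  tau <- 20
  total <- nVol * trVol
  hFine <- numeric(total)
  hCur <- 0
  cycle <- 0L
  blockStartH <- 0
  blockStartT <- 0
  prevBh <- FALSE
  for (s in seq_len(total)) {
    t <- s - 1
    vol <- floor(t / trVol) + 1
    inBh <- cond[vol] == "bh"
    if (inBh && !prevBh) {
      cycle <- cycle + 1L
      blockStartH <- hCur
      blockStartT <- t
    }
    if (inBh) {
      frac <- min((t - blockStartT + 1) / paradigm@onDuration, 1)
      hCur <- blockStartH + (peaks[cycle] - blockStartH) * frac
    } else {
      hCur <- hCur * exp(-1 / tau)
    }
    hFine[s] <- hCur
    prevBh <- inBh
  }
  mid <- pmin(pmax(round((seq_len(nVol) - 0.5) * trVol), 1), total)
  data.frame(volume = seq_len(nVol), onset = onset, condition = cond,
             h = hFine[mid])
}

# Core generator shared by the BH and task simulators. cbvJitterSd adds
# multiplicative volume-to-volume variability to the CBV response (vascular
# tone fluctuation), scaled by the hypercapnia level so baseline volumes are
# untouched; it decouples r_cbv from r_cbf across time points, which is what
# makes M and beta jointly identifiable in the calibration fit.
buildRun <- function(physio, acq, paradigm, noiseSd, nRuns, voxelsPerLayer,
                     driftSlope = 0, outlierRate = 0, outlierAmp = 0.05,
                     cbvJitterSd = 0) {
  noiseSd <- rep_len(noiseSd, 3)
  stopIfNot(all(noiseSd >= 0), "noiseSd must be >= 0")
  nL <- physio@nLayers
  labels <- rep(seq_len(nL), each = voxelsPerLayer)
  nVox <- length(labels)
  trVol <- acq@volumeTrAslVaso

  volList <- list(); volBoldList <- list()
  aslList <- list(); vasoList <- list(); boldList <- list()

  for (r in seq_len(nRuns)) {
    sched <- hypercapniaSchedule(paradigm, trVol)
    nVol <- nrow(sched)
    # per-layer ratios per volume
    hRow <- matrix(sched$h, nrow = nL, ncol = nVol, byrow = TRUE)
    rCbf <- 1 + hRow * (physio@cbfResponse - 1)
    rCbv <- if (is.null(physio@cbvResponse)) {
      rCbf^physio@grubbAlpha
    } else {
      1 + hRow * (physio@cbvResponse - 1)
    }
    if (cbvJitterSd > 0) {
      jit <- exp(sched$h * stats::rnorm(nVol, 0, cbvJitterSd))
      rCbv <- rCbv * matrix(jit, nrow = nL, ncol = nVol, byrow = TRUE)
    }
    rCmro2 <- 1 + hRow * (physio@cmro2Response - 1)

    aslDiff <- vaso <- bold1 <- matrix(0, nL, nVol)
    for (v in seq_len(nVol)) {
      fs <- forwardSignals(physio, acq, rCbf[, v], rCbv[, v], rCmro2[, v])
      aslDiff[, v] <- fs$aslDiffOverM0
      vaso[, v] <- fs$vaso
      bold1[, v] <- fs$bold
    }

    # expand to voxels
    aslDiffVox <- aslDiff[labels, , drop = FALSE]
    vasoVox <- vaso[labels, , drop = FALSE]
    boldVox1 <- bold1[labels, , drop = FALSE]

    # interleaved control/label in M0 units: control = 1, label = 1 - dM/M0
    asl <- matrix(0, nVox, 2L * nVol)
    asl[, 2L * seq_len(nVol) - 1L] <- 1
    asl[, 2L * seq_len(nVol)] <- 1 - aslDiffVox
    # BOLD at half the volume TR: two volumes share the volume's state
    bold <- matrix(0, nVox, 2L * nVol)
    bold[, 2L * seq_len(nVol) - 1L] <- boldVox1
    bold[, 2L * seq_len(nVol)] <- boldVox1

    # linear drift per run (VASO/BOLD; added to both ASL control and label so
    # that pairwise subtraction cancels it, as it does in vivo)
    if (driftSlope != 0) {
      tV <- sched$onset + trVol / 2
      tB <- rep(sched$onset, each = 2) + rep(c(0.25, 0.75), nVol) * trVol
      vasoVox <- vasoVox + matrix(driftSlope * tV, nVox, nVol, byrow = TRUE)
      bold <- bold + matrix(driftSlope * tB, nVox, 2L * nVol, byrow = TRUE)
      asl <- asl + matrix(driftSlope * rep(tV, each = 2), nVox, 2L * nVol,
                          byrow = TRUE)
    }

    # noise
    if (noiseSd[1] > 0)
      asl <- asl + matrix(stats::rnorm(length(asl), 0, noiseSd[1]),
                          nVox, 2L * nVol)
    if (noiseSd[2] > 0)
      vasoVox <- vasoVox + matrix(stats::rnorm(length(vasoVox), 0,
                                               noiseSd[2]), nVox, nVol)
    if (noiseSd[3] > 0)
      bold <- bold + matrix(stats::rnorm(length(bold), 0, noiseSd[3]),
                            nVox, 2L * nVol)

    # outlier spikes on VASO/BOLD volumes, flagged in the metadata
    outlier <- rep(FALSE, nVol)
    if (outlierRate > 0) {
      outlier <- stats::runif(nVol) < outlierRate
      for (v in which(outlier)) {
        vasoVox[, v] <- vasoVox[, v] + outlierAmp
        bold[, 2L * v - 1L] <- bold[, 2L * v - 1L] + outlierAmp
      }
    }

    volList[[r]] <- data.frame(run = r, sched, outlier = outlier)
    volBoldList[[r]] <- data.frame(
      run = r, volume = seq_len(2L * nVol),
      onset = rep(sched$onset, each = 2) + rep(c(0, trVol / 2), nVol),
      condition = rep(sched$condition, each = 2),
      h = rep(sched$h, each = 2),
      outlier = rep(outlier, each = 2)
    )
    aslList[[r]] <- asl; vasoList[[r]] <- vasoVox; boldList[[r]] <- bold
  }

  new("MultiContrastRun",
    asl = do.call(cbind, aslList),
    vaso = do.call(cbind, vasoList),
    bold = do.call(cbind, boldList),
    volumes = do.call(rbind, volList),
    volumesBold = do.call(rbind, volBoldList),
    layerLabels = labels,
    m0 = rep(1, nVox),
    acquisition = acq,
    truth = physio,
    meta = list(noiseSd = noiseSd, driftSlope = driftSlope,
                outlierRate = outlierRate, outlierAmp = outlierAmp,
                paradigm = paradigm)
  )
}

#' Simulate a breath-hold calibration acquisition
#'
#' Forward-models ASL, VASO and BOLD voxel time series for a breath-hold
#' hypercapnia experiment. The hypercapnia level h(t) in \[0, 1\] follows
#' either a `"ramped"` profile — linear ramp over each 24 s block to a
#' cycle-specific peak drawn from U(0.7, 1), exponential recovery with a
#' 20 s time constant between blocks, so nominal rest periods retain
#' residual hypercapnia — or an idealized `"plateau"` square wave reaching
#' full depth. The ramped profile makes (r_CBF, r_CBV) pairs span a range so
#' that M and beta are jointly identifiable. Per-layer response ratios scale
#' with h: `r = 1 + h * (peak - 1)`; CBV is Grubb-coupled to CBF when the
#' physiology does not specify it explicitly. CMRO2 responses follow the
#' physiology (unity in the `bh_default` scenario: hypercapnia is assumed
#' iso-metabolic).
#'
#' @param physio a [LayerPhysiology-class].
#' @param acq an [AcquisitionConfig-class].
#' @param paradigm a breath-hold [ParadigmSpec-class].
#' @param noiseSd additive Gaussian noise SD per contrast,
#'   `c(asl, vaso, bold)`, in M0 units (i.i.d. per voxel and time point).
#' @param seed integer seed for reproducibility.
#' @param nRuns number of runs (2 runs of the default paradigm give the 54
#'   co-sampled calibration points).
#' @param voxelsPerLayer voxels simulated per layer.
#' @param cbvJitterSd SD of the multiplicative volume-to-volume variability
#'   of the CBV response (vascular tone fluctuation), applied in proportion
#'   to the hypercapnia level. This physiological decoupling of r_CBV from
#'   r_CBF across time points is what renders M and beta jointly
#'   identifiable; without it the (r_CBF, r_CBV) pairs lie on a single
#'   trajectory and only their product with M is determined. Set to 0 for an
#'   idealized perfectly coupled run.
#' @return a [MultiContrastRun-class] with the ground truth attached.
#' @examples
#' run <- simulateBreathHoldRun(makePhysiology(8, "bh_default"), seed = 1)
#' run
#' @export
simulateBreathHoldRun <- function(physio,
                                  acq = acquisitionConfig(),
                                  paradigm = bhParadigm(),
                                  noiseSd = c(asl = 0.002, vaso = 0.005,
                                              bold = 0.005),
                                  seed = NULL,
                                  nRuns = 2,
                                  voxelsPerLayer = 50,
                                  cbvJitterSd = 0.03) {
  stopIfNot(paradigm@blockType == "breath_hold",
            "paradigm must be a breath_hold design")
  withSeed(seed,
           buildRun(physio, acq, paradigm, noiseSd, nRuns, voxelsPerLayer,
                    cbvJitterSd = cbvJitterSd))
}

#' Simulate a block-design task acquisition
#'
#' Forward-models ASL, VASO and BOLD series for an interleaved rest/task
#' block design (finger-tapping style). On-blocks apply the physiology's
#' response ratios in full; off-blocks are at baseline (the state switches
#' instantaneously with the block). Optionally adds a linear drift per run
#' (to VASO, BOLD, and equally to ASL control and label so pairwise
#' subtraction cancels it) and injects outlier spike volumes flagged in the
#' metadata, for preprocessing tests.
#'
#' @inheritParams simulateBreathHoldRun
#' @param paradigm a task [ParadigmSpec-class].
#' @param driftSlope linear drift in signal units per second (per run).
#' @param outlierRate probability that a VASO/BOLD volume is a spike.
#' @param outlierAmp spike amplitude in M0 units.
#' @return a [MultiContrastRun-class].
#' @examples
#' run <- simulateTaskRun(makePhysiology(15, "task_two_peak"),
#'                        noiseSd = c(0, 0, 0), seed = 1)
#' @export
simulateTaskRun <- function(physio,
                            acq = acquisitionConfig(),
                            paradigm = taskParadigm(),
                            noiseSd = c(asl = 0.002, vaso = 0.005,
                                        bold = 0.005),
                            seed = NULL,
                            nRuns = 1,
                            voxelsPerLayer = 50,
                            driftSlope = 0,
                            outlierRate = 0,
                            outlierAmp = 0.05) {
  stopIfNot(paradigm@blockType == "task_block",
            "paradigm must be a task_block design")
  withSeed(seed,
           buildRun(physio, acq, paradigm, noiseSd, nRuns, voxelsPerLayer,
                    driftSlope, outlierRate, outlierAmp))
}
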