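# Signal conditioning: pairwise ASL subtraction, detrending, percentile
# capping, SVD slice-deblurring, breath-hold delay estimation.

#' Pairwise control-label subtraction of an interleaved ASL series
#'
#' Each adjacent (control, label) pair yields one perfusion-weighted point:
#' `control - label`. The output has half as many time points as the input.
#'
#' @param aslSeries voxels x time matrix (or vector) of interleaved
#'   control/label volumes, control first.
#' @return voxels x pairs matrix (or vector) of perfusion-weighted
#'   differences.
#' @export
pairwiseSubtract <- function(aslSeries) {
  vecIn <- is.null(dim(aslSeries))
  x <- rbind(aslSeries)[, , drop = FALSE]
  nT <- ncol(x)
  if (nT %% 2L != 0L)
    stop("interleaved ASL series must have an even number of time points",
         call. = FALSE)
  out <- x[, seq(1L, nT, by = 2L), drop = FALSE] -
    x[, seq(2L, nT, by = 2L), drop = FALSE]
  if (vecIn) drop(out) else out
}

#' Remove a polynomial trend from one run
#'
#' Fits and removes a least-squares polynomial of the given order per voxel,
#' then restores the run mean, suppressing low-frequency physiological
#' drift. Intended for VASO and BOLD series of a single run; perfusion
#' series need no detrending because pairwise subtraction already removes
#' slow drifts.
#'
#' @param series voxels x time matrix (or vector) of one run.
#' @param order polynomial order (1 = linear).
#' @return detrended series, same shape, with per-voxel means preserved.
#' @export
detrendRun <- function(series, order = 1) {
  vecIn <- is.null(dim(series))
  x <- rbind(series)[, , drop = FALSE]
  nT <- ncol(x)
  stopIfNot(order < nT, "order must be smaller than the number of time points")
  tt <- seq_len(nT)
  basis <- stats::poly(tt, degree = order)
  fit <- stats::lm.fit(cbind(1, basis), t(x))
  resid <- t(fit$residuals) + rowMeans(x)
  if (vecIn) drop(resid) else resid
}

#' Cap outliers at percentile bounds
#'
#' Values below the `loPct` percentile are set to it and values above the
#' `hiPct` percentile are set to it, per voxel, with percentiles computed
#' across all supplied time points (pool rest and task runs before calling).
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Conventional bounds: (15, 85) for BOLD and
#' VASO, (25, 75) for ASL perfusion series.
#'
#' @param series voxels x time matrix (or vector).
#' @param loPct,hiPct percentile bounds in \[0, 100\], `loPct < hiPct`.
#' @return capped series, same shape.
#' @examples
#' capOutliers(1:10, 25, 75)
#' @export
capOutliers <- function(series, loPct, hiPct) {
  stopIfNot(loPct >= 0 && hiPct <= 100 && loPct < hiPct,
            "need 0 <= loPct < hiPct <= 100")
  vecIn <- is.null(dim(series))
  x <- rbind(series)[, , drop = FALSE]
  if (ncol(x) == 0) stop("empty series", call. = FALSE)
  for (i in seq_len(nrow(x))) {
    q <- stats::quantile(x[i, ], c(loPct, hiPct) / 100, names = FALSE,
                         type = 7)
    x[i, ] <- pmin(pmax(x[i, ], q[1]), q[2])
  }
  if (vecIn) drop(x) else x
}

#' Slice-direction blur operator induced by arterial T2 decay
#'
#' The 3D GRASE readout acquires partition (slice) encodes sequentially over
#' the echo train; the short arterial T2 at 7T weights encode i by
#' `w_i = exp(-(TE + t_i)/T2)` with `t_i = (i - 1) * echoSpacing` in
#' acquisition order. Under `"centric"` ordering the k-space center is
#' acquired first and successive encodes alternate outward; `"linear"`
#' acquires k bottom-to-top. The image-space operator is the circulant
#' convolution `Re(F^-1 diag(w_k) F)` along the slice axis.
#'
#' @param nSlices number of slices (>= 2).
#' @param t2Arterial arterial T2 in seconds (`Inf` gives the identity).
#' @param echoSpacing inter-encode spacing in seconds.
#' @param echoTime time of the first encode in seconds.
#' @param ordering `"centric"` or `"linear"`.
#' @return nSlices x nSlices real blur matrix.
#' @export
sliceBlurOperator <- function(nSlices, t2Arterial = 0.068,
                              echoSpacing = 0.010, echoTime = 0.0172,
                              ordering = c("centric", "linear")) {
  ordering <- match.arg(ordering)
  n <- as.integer(nSlices)
  stopIfNot(n >= 2L, "nSlices must be >= 2")
  kIndex <- seq_len(n) - 1L - n %/% 2L      # -n/2 .. n/2-1
  if (ordering == "centric") {
    acqOrder <- order(abs(kIndex), kIndex)  # center out, |k| ascending
  } else {
    acqOrder <- seq_len(n)                  # bottom-to-top
  }
  tAcq <- numeric(n)
  tAcq[acqOrder] <- echoTime + (seq_len(n) - 1L) * echoSpacing
  w <- exp(-tAcq / t2Arterial)              # weight per k index
  # circulant operator: rows of F are exp(-2*pi*i*k*x/n) over k
  kShift <- kIndex
  A <- matrix(0, n, n)
  x <- seq_len(n) - 1L
  for (j in seq_len(n)) {
    # PSF column: inverse DFT of w at spatial offset (x - j + 1)
    shift <- (x - (j - 1L))
    A[, j] <- Re(colSums(w * exp(2i * pi * outer(kShift, shift) / n))) / n
  }
  A
}

#' SVD-based slice-direction deblurring
#'
#' Inverts the T2-decay blur operator of [sliceBlurOperator()] by truncated
#' SVD: singular components with singular value below
#' `threshold * max(singular values)` are discarded, so blur is removed
#' without amplifying noise in near-null directions. With `threshold = 0`
#' this is the exact (pseudo-)inverse on the operator's row space.
#'
#' @param volumeStack matrix with slices along rows (nSlices x anything):
#'   each column is deblurred independently; a vector is treated as one
#'   profile.
#' @param nSlices number of slices; defaults to `nrow(volumeStack)`.
#' @param threshold truncation threshold as a fraction of the largest
#'   singular value, in \[0, 1\].
#' @param ... passed to [sliceBlurOperator()] (`t2Arterial`, `echoSpacing`,
#'   `echoTime`, `ordering`).
#' @return deblurred stack, same shape.
#' @export
svdDeblur <- function(volumeStack, nSlices = NULL, threshold = 0.1, ...) {
  stopIfNot(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  vecIn <- is.null(dim(volumeStack))
  x <- cbind(volumeStack)
  if (is.null(nSlices)) nSlices <- nrow(x)
  stopIfNot(nrow(x) == nSlices, "stack must have nSlices rows")
  A <- sliceBlurOperator(nSlices, ...)
  sv <- svd(A)
  keep <- sv$d >= threshold * sv$d[1] & sv$d > .Machine$double.eps * sv$d[1]
  if (!any(keep))
    stop("blur operator is singular at this threshold", call. = FALSE)
  dInv <- ifelse(keep, 1 / sv$d, 0)
  out <- sv$v %*% (dInv * crossprod(sv$u, x))
  if (vecIn) drop(out) else out
}

#' Estimate the breath-hold response delay
#'
#' Cross-correlates the mean BOLD series with the paradigm's block regressor
#' and returns the non-negative lag (in seconds) that maximizes the
#' correlation, at the resolution of the sampling interval. Used on a
#' pre-scan to shift breath-hold cues so that acquisitions sample the
#' dilated state.
#'
#' @param boldSeries numeric vector (mean BOLD time course) or voxels x time
#'   matrix (averaged over voxels first).
#' @param paradigm a [ParadigmSpec-class] describing the block design.
#' @param tr sampling interval of `boldSeries` in seconds.
#' @param maxLag maximum lag searched, seconds (default one off-block).
#' @return delay in seconds.
#' @export
estimateBreathHoldDelay <- function(boldSeries, paradigm, tr = 1,
                                    maxLag = paradigm@offDuration) {
  y <- if (is.null(dim(boldSeries))) as.numeric(boldSeries)
       else colMeans(boldSeries)
  if (stats::sd(y) == 0)
    stop("flat BOLD series: breath-hold lag is undefined", call. = FALSE)
  nT <- length(y)
  tt <- (seq_len(nT) - 1L) * tr
  cycle <- paradigm@onDuration + paradigm@offDuration
  inBlock <- function(t) {
    tc <- t - paradigm@leadIn
    tc >= 0 & (tc %% cycle) >= paradigm@offDuration
  }
  reg <- as.numeric(inBlock(tt))
  if (stats::sd(reg) == 0)
    stop("paradigm regressor is constant over the series", call. = FALSE)
  lags <- seq(0L, floor(maxLag / tr))
  cc <- vapply(lags, function(L) {
    if (L >= nT - 2) return(-Inf)
    yl <- y[(L + 1):nT]; rl <- reg[1:(nT - L)]
    if (stats::sd(yl) == 0) return(-Inf)
    stats::cor(yl, rl)
  }, numeric(1))
  if (all(!is.finite(cc)))
    stop("no valid lag: series too short or degenerate", call. = FALSE)
  best <- which.max(cc)
  # guard against meaningless lags from noise-only input: the best
  # correlation must survive a Bonferroni-corrected significance test
  L <- lags[best]
  ct <- stats::cor.test(y[(L + 1):nT], reg[1:(nT - L)])
  if (is.na(ct$p.value) || ct$p.value * length(lags) > 0.05)
    stop("no reliable breath-hold lag: series does not follow the block ",
         "regressor", call. = FALSE)
  L * tr
}
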