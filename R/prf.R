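# Grid-based population receptive field estimation.

#' Visual-field sampling grid
#'
#' Samples the visual field into an n x n grid of square cells. The default
#' 40 x 40 grid spans -10..10 degrees with 0.5-degree cells, realized as
#' cell centers at -9.75, -9.25, ..., 9.75 on both axes.
#'
#' @param nCells cells per axis.
#' @param halfWidth half-extent of the field in degrees.
#' @return list with `x`, `y` (cell-center coordinates of all nCells^2
#'   cells, column-major), `centers` (per-axis centers), `cellSize`,
#'   `nCells`.
#' @export
visualFieldGrid <- function(nCells = 40, halfWidth = 10) {
  cellSize <- 2 * halfWidth / nCells
  centers <- -halfWidth + (seq_len(nCells) - 0.5) * cellSize
  list(
    x = rep(centers, times = nCells),
    y = rep(centers, each = nCells),
    centers = centers,
    cellSize = cellSize,
    nCells = as.integer(nCells)
  )
}

#' Node time series of a sweeping-bar stimulus
#'
#' A bar sweeps across the visual field in `nSteps` steps per sweep; after
#' each sweep its orientation rotates by `rotationStep` degrees. At each
#' time point (one per TR) the indicator marks the grid cells covered by the
#' bar. Because the bar moves continuously between the discrete samplings,
#' each time point covers the half-open window of the sweep axis closest to
#' its bar position (at least the bar's own width): with the default
#' one-cell bar every cell is stimulated exactly once per sweep.
#'
#' @param grid a [visualFieldGrid()].
#' @param nSweeps number of sweeps.
#' @param nSteps steps (time points) per sweep.
#' @param rotationStep rotation between sweeps, degrees.
#' @param barWidth bar width in grid cells.
#' @return binary matrix, nodes x time (`nCells^2` x `nSweeps * nSteps`).
#' @examples
#' grid <- visualFieldGrid()
#' node <- buildStimulusNodeSeries(grid, nSweeps = 1)
#' dim(node)  # 1600 x 30
#' @export
buildStimulusNodeSeries <- function(grid = visualFieldGrid(), nSweeps = 8,
                                    nSteps = 30, rotationStep = 15,
                                    barWidth = 1) {
  if (nSweeps == 0)
    return(matrix(0, grid$nCells^2, 0))
  out <- matrix(0, grid$nCells^2, nSweeps * nSteps)
  halfBar <- barWidth * grid$cellSize / 2
  for (s in seq_len(nSweeps)) {
    theta <- (s - 1) * rotationStep * pi / 180
    nx <- cos(theta); ny <- sin(theta)   # sweep direction (bar normal)
    proj <- grid$x * nx + grid$y * ny    # signed distance along the normal
    # the sweep spans the whole stimulated field along its direction
    halfSpan <- max(abs(proj)) + grid$cellSize / 2
    positions <- seq(-halfSpan, halfSpan, length.out = nSteps)
    spacing <- if (nSteps > 1) positions[2] - positions[1] else 2 * halfSpan
    # assign every cell to its nearest bar position (the bar moves
    # continuously between samplings), plus any cell inside the bar itself
    nearest <- pmin(pmax(round((proj + halfSpan) / spacing), 0),
                    nSteps - 1) + 1
    for (k in seq_len(nSteps)) {
      covered <- nearest == k | abs(proj - positions[k]) <= halfBar
      out[covered, (s - 1) * nSteps + k] <- 1
    }
  }
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities peaking at 5 s (response) and 15 s
#' (undershoot, weighted 1/6), sampled at the acquisition TR and normalized
#' to unit peak.
#'
#' @param tr sampling interval, seconds.
#' @param duration HRF support, seconds.
#' @return numeric vector of HRF samples.
#' @export
canonicalHrf <- function(tr = 1.2, duration = 30) {
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Ridge-regularized deconvolution of a voxel time series
#'
#' Inverts the convolution with the HRF by Tikhonov-regularized least
#' squares: with `C` the (causal) convolution operator, the neural series is
#' `argmin ||C x - y||^2 + ridge * smax^2 ||x||^2` where `smax` is the
#' largest singular value of `C`. At small ridge, re-convolving the output
#' approximates the input.
#'
#' @param ts observed time series (vector) or voxels x time matrix.
#' @param hrf HRF samples at the series' TR (shorter than the series).
#' @param ridge regularization as a fraction of `smax^2`.
#' @return deconvolved series, same shape.
#' @export
deconvolveVoxel <- function(ts, hrf, ridge = 0.01) {
  vecIn <- is.null(dim(ts))
  Y <- rbind(ts)[, , drop = FALSE]
  nT <- ncol(Y)
  stopIfNot(nT > 0, "empty series")
  stopIfNot(length(hrf) < nT, "hrf must be shorter than the series")
  C <- matrix(0, nT, nT)
  for (k in seq_along(hrf)) {
    idx <- seq_len(nT - k + 1L)
    C[cbind(idx + k - 1L, idx)] <- hrf[k]
  }
  sv <- svd(C)
  shrink <- sv$d / (sv$d^2 + ridge * sv$d[1]^2)
  out <- t(sv$v %*% (shrink * crossprod(sv$u, t(Y))))
  if (vecIn) drop(out) else out
}

#' Receptive-field map and center of one voxel
#'
#' Regresses the (deconvolved) neural time series on each grid node's
#' indicator series to obtain the voxel's response to stimulation at each
#' node, then extracts the receptive-field center as the response-weighted
#' centroid of the cells above half the maximum response. Eccentricity and
#' polar angle follow from the center coordinates.
#'
#' @param neuralTs deconvolved time series of one voxel.
#' @param nodeSeries nodes x time indicator matrix from
#'   [buildStimulusNodeSeries()].
#' @param grid the [visualFieldGrid()] matching `nodeSeries`.
#' @return data.frame with `x`, `y`, `eccentricity`, `polarAngle`
#'   (degrees), `peakResponse`.
#' @export
rfMapAndCenter <- function(neuralTs, nodeSeries, grid = visualFieldGrid()) {
  stopIfNot(length(neuralTs) == ncol(nodeSeries),
            "neural series and node series must share the time axis")
  y <- neuralTs - mean(neuralTs)
  X <- nodeSeries - rowMeans(nodeSeries)
  varX <- rowSums(X^2)
  resp <- as.numeric(X %*% y) / pmax(varX, .Machine$double.eps)
  resp[varX == 0] <- 0
  peak <- max(resp)
  if (peak <= 0 || stats::sd(resp) == 0)
    stop("degenerate receptive-field map: no positive response structure",
         call. = FALSE)
  keep <- resp >= peak / 2
  w <- resp[keep]
  x0 <- sum(w * grid$x[keep]) / sum(w)
  y0 <- sum(w * grid$y[keep]) / sum(w)
  data.frame(
    x = x0, y = y0,
    eccentricity = sqrt(x0^2 + y0^2),
    polarAngle = atan2(y0, x0) * 180 / pi,
    peakResponse = peak
  )
}

#' Eccentricity-band ROI assignment
#'
#' Assigns each voxel to the eccentricity bin containing its pRF center
#' (default 1-degree bands from 0 to 8 degrees); eccentricities outside the
#' bins are unassigned (`NA`).
#'
#' @param prfResults data.frame with an `eccentricity` column (rows =
#'   voxels), e.g. stacked [rfMapAndCenter()] results.
#' @param bins bin edges in degrees.
#' @return integer bin index per voxel (1 = first bin), `NA` if outside.
#' @examples
#' eccRois(data.frame(eccentricity = c(4.5, 9.5)))  # 5, NA
#' @export
eccRois <- function(prfResults, bins = 0:8) {
  ecc <- prfResults$eccentricity
  stopIfNot(all(is.finite(ecc)), "eccentricities must be finite")
  idx <- findInterval(ecc, bins, rightmost.closed = FALSE)
  idx[idx < 1L | idx >= length(bins)] <- NA_integer_
  as.integer(idx)
}

#' Simulate voxel time series with known receptive fields
#'
#' Forward model for pRF recovery tests: each voxel responds with a
#' Gaussian receptive field centered at a known position, the node series is
#' weighted accordingly, convolved with the HRF, and Gaussian noise is added
#' at a specified SNR (SD of the clean series divided by the noise SD).
#'
#' @param centers data.frame with columns `x`, `y` (degrees), one row per
#'   voxel.
#' @param nodeSeries nodes x time matrix.
#' @param grid matching [visualFieldGrid()].
#' @param sigma receptive-field width in degrees.
#' @param hrf HRF samples.
#' @param snr signal-to-noise ratio; `Inf` for noiseless.
#' @param seed integer seed.
#' @return voxels x time matrix.
#' @export
simulatePrfVoxels <- function(centers, nodeSeries, grid = visualFieldGrid(),
                              sigma = 0.75, hrf = canonicalHrf(),
                              snr = Inf, seed = NULL) {
  withSeed(seed, {
    nT <- ncol(nodeSeries)
    out <- matrix(0, nrow(centers), nT)
    for (v in seq_len(nrow(centers))) {
      w <- exp(-((grid$x - centers$x[v])^2 + (grid$y - centers$y[v])^2) /
                 (2 * sigma^2))
      neural <- as.numeric(crossprod(nodeSeries, w))
      clean <- stats::convolve(neural, rev(hrf), type = "open")[seq_len(nT)]
      if (is.finite(snr)) {
        clean <- clean + stats::rnorm(nT, 0, stats::sd(clean) / snr)
      }
      out[v, ] <- clean
    }
    out
  })
}
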