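# NIfTI/TSV/JSON serialization of runs and results.

numTsvWrite <- function(df, path) {
  # full-precision numeric formatting so that a write/read roundtrip is
  # bit-exact
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a multi-contrast run to a directory
#'
#' Serializes a [MultiContrastRun-class] as NIfTI volumes (one 4D file per
#' contrast, voxels along the first axis; M0 and integer layer labels as 3D
#' files), TSV sidecar tables of per-volume condition labels, and JSON
#' records of the acquisition configuration and (if present) the
#' ground-truth physiology. The roundtrip through
#' [readMultiContrastRun()] is bit-exact.
#'
#' @param run a [MultiContrastRun-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeMultiContrastRun <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(mat, name) {
    arr <- array(mat, dim = c(nrow(mat), 1L, 1L, ncol(mat)))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"),
                       file.path(dir, name))
  }
  wr(run@asl, "asl.nii.gz")
  wr(run@vaso, "vaso.nii.gz")
  wr(run@bold, "bold.nii.gz")
  RNifti::writeNifti(
    RNifti::asNifti(array(run@m0, dim = c(length(run@m0), 1L, 1L)),
                    datatype = "double"),
    file.path(dir, "m0.nii.gz"))
  RNifti::writeNifti(
    RNifti::asNifti(array(as.integer(run@layerLabels),
                          dim = c(length(run@layerLabels), 1L, 1L)),
                    datatype = "int32"),
    file.path(dir, "layers.nii.gz"))
  numTsvWrite(run@volumes, file.path(dir, "volumes.tsv"))
  numTsvWrite(run@volumesBold, file.path(dir, "volumes_bold.tsv"))
  acq <- run@acquisition
  jsonlite::write_json(
    list(
      labelingDuration = acq@labelingDuration,
      postLabelingDelay = acq@postLabelingDelay,
      t1Blood = acq@t1Blood,
      lambdaPartition = acq@lambdaPartition,
      labelingEfficiency = acq@labelingEfficiency,
      bsInversionEfficiency = acq@bsInversionEfficiency,
      t2Arterial = acq@t2Arterial,
      volumeTrAslVaso = acq@volumeTrAslVaso,
      volumeTrBold = acq@volumeTrBold,
      echoTime = acq@echoTime,
      nSlices = acq@nSlices
    ),
    file.path(dir, "acquisition.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(run@truth)) {
    tr <- run@truth
    truthList <- list(
        nLayers = tr@nLayers,
        baselineCbf = tr@baselineCbf,
        baselineCbv = tr@baselineCbv,
        davisM = tr@davisM,
        davisBeta = tr@davisBeta,
        cbfResponse = tr@cbfResponse,
        cbvResponse = tr@cbvResponse,
        cmro2Response = tr@cmro2Response,
        grubbAlpha = tr@grubbAlpha,
        scenario = tr@scenario
      )
    if (is.null(tr@cbvResponse)) truthList$cbvResponse <- NULL
    jsonlite::write_json(truthList, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a multi-contrast run from a directory
#'
#' Inverse of [writeMultiContrastRun()], with validation: contrasts must
#' share the voxel dimension, the sidecar tables must match the volume
#' counts, and M0 must be present.
#'
#' @param dir directory written by [writeMultiContrastRun()].
#' @return a [MultiContrastRun-class].
#' @export
readMultiContrastRun <- function(dir) {
  need <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p))
      stop(sprintf("missing file '%s' in %s", name, dir), call. = FALSE)
    p
  }
  if (!file.exists(file.path(dir, "m0.nii.gz")))
    stop(sprintf("missing M0 calibration volume (m0.nii.gz) in %s", dir),
         call. = FALSE)
  rd <- function(name) {
    arr <- as.array(RNifti::readNifti(need(name)))
    matrix(arr, nrow = dim(arr)[1])
  }
  asl <- rd("asl.nii.gz"); vaso <- rd("vaso.nii.gz"); bold <- rd("bold.nii.gz")
  m0 <- as.numeric(as.array(RNifti::readNifti(need("m0.nii.gz"))))
  layers <- as.integer(as.array(RNifti::readNifti(need("layers.nii.gz"))))
  volumes <- utils::read.delim(need("volumes.tsv"))
  volumesBold <- utils::read.delim(need("volumes_bold.tsv"))
  if (nrow(volumes) != ncol(vaso))
    stop(sprintf(
      "volume count mismatch: %d VASO volumes but %d rows in volumes.tsv",
      ncol(vaso), nrow(volumes)), call. = FALSE)
  if (nrow(volumesBold) != ncol(bold))
    stop(sprintf(
      "volume count mismatch: %d BOLD volumes but %d rows in volumes_bold.tsv",
      ncol(bold), nrow(volumesBold)), call. = FALSE)
  nBad <- sum(!is.finite(asl)) + sum(!is.finite(vaso)) + sum(!is.finite(bold))
  if (nBad > 0)
    stop(sprintf("%d non-finite voxel values in input volumes", nBad),
         call. = FALSE)
  acqj <- jsonlite::read_json(need("acquisition.json"), simplifyVector = TRUE)
  acq <- do.call(acquisitionConfig, acqj)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    cbvResp <- tj$cbvResponse
    if (length(cbvResp) == 0) cbvResp <- NULL   # Grubb-coupled truth
    truth <- layerPhysiology(
      nLayers = tj$nLayers, baselineCbf = tj$baselineCbf,
      baselineCbv = tj$baselineCbv, davisM = tj$davisM,
      davisBeta = tj$davisBeta, cbfResponse = tj$cbfResponse,
      cbvResponse = cbvResp, cmro2Response = tj$cmro2Response,
      grubbAlpha = tj$grubbAlpha, scenario = tj$scenario
    )
  }
  new("MultiContrastRun",
    asl = asl, vaso = vaso, bold = bold,
    volumes = volumes, volumesBold = volumesBold,
    layerLabels = layers, m0 = m0, acquisition = acq, truth = truth,
    meta = list()
  )
}
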