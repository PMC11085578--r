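#' @include quantify.R
NULL

.checkNiftiPath <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop(sprintf("format error: '%s' is not a NIfTI path (.nii or .nii.gz)", path))
  invisible(path)
}

#' Write a volume as NIfTI-1
#'
#' Writes the magnitude (or concentration) volume as float32 NIfTI-1 with
#' the voxel size recorded in the header (mm). The float32 payload
#' round-trips bit-identically through [readImage()].
#'
#' @param image a [ReconImage-class] or [ConcentrationMap-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path) {
  .checkNiftiPath(path)
  arr <- imageData(image)
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- voxelSize(image) * 1e3
  RNifti::writeNifti(nii, path, datatype = "float")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI path written by [writeImage()] (or any 3D NIfTI).
#' @return A [ReconImage-class]; voxel size is taken from the header
#'   (converted from mm to m).
#' @export
readImage <- function(path) {
  .checkNiftiPath(path)
  if (!file.exists(path)) stop(sprintf("I/O error reading '%s': file not found", path))
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim = dim(nii))
  new("ReconImage", data = abs(arr),
      complexData = array(complex(0), dim = c(0, 0, 0)),
      voxelSize = RNifti::pixdim(nii)[1:3] / 1e3,
      provenance = list(path = path))
}

.KSPACE_SCHEMA <- "sodiumQA-kspace-v1"

#' Persist / restore a k-space dataset
#'
#' Serializes a [KSpaceDataset-class] (samples, trajectory arrays,
#' parameters, noise level, seed, identifiers) as a single-file container
#' with a versioned schema string, and restores it. The layout is a named
#' list: `schema`, `samples`, `trajectory` (directions, kRadial,
#' sampleTimes, kmax, densityWeights), `params`, `noiseSigma`, `seed`,
#' `sessionId`, `repeatIds`.
#'
#' @param dataset a [KSpaceDataset-class].
#' @param path file path (`.rds`).
#' @return `saveDataset()` returns `path` invisibly; `loadDataset()` the
#'   restored [KSpaceDataset-class].
#' @export
saveDataset <- function(dataset, path) {
  stopifnot(is(dataset, "KSpaceDataset"))
  tr <- dataset@trajectory
  obj <- list(schema = .KSPACE_SCHEMA,
              samples = dataset@samples,
              trajectory = list(directions = tr@directions, kRadial = tr@kRadial,
                                sampleTimes = tr@sampleTimes, kmax = tr@kmax,
                                densityWeights = tr@densityWeights),
              params = dataset@params, noiseSigma = dataset@noiseSigma,
              seed = dataset@seed, sessionId = dataset@sessionId,
              repeatIds = dataset@repeatIds)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error reading '%s': file not found", path))
  obj <- readRDS(path)
  if (!identical(obj$schema, .KSPACE_SCHEMA))
    stop(sprintf("unsupported k-space container schema '%s'", obj$schema))
  tr <- new("TrajectorySet", directions = obj$trajectory$directions,
            kRadial = obj$trajectory$kRadial,
            sampleTimes = obj$trajectory$sampleTimes,
            kmax = obj$trajectory$kmax,
            densityWeights = obj$trajectory$densityWeights)
  new("KSpaceDataset", samples = obj$samples, trajectory = tr,
      params = obj$params, noiseSigma = obj$noiseSigma, seed = obj$seed,
      sessionId = obj$sessionId, repeatIds = obj$repeatIds)
}

#' Serialize an ROI set to a JSON sidecar
#'
#' @param rois an [ROISet-class].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writeROIs <- function(rois, path) {
  stopifnot(is(rois, "ROISet"))
  obj <- list(vialROIs = rois@vialROIs, noiseROIs = rois@noiseROIs,
              slice = rois@slice, gridShape = rois@gridShape,
              voxelSize = rois@voxelSize)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Export per-vial concentration estimates as CSV
#'
#' Fixed column layout: `label`, `size`, `nominal_mM`, `estimated_mM`, `sd`.
#'
#' @param estimates data.frame from [estimateVialConcentrations()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
writeEstimatesCSV <- function(estimates, path) {
  out <- data.frame(label = estimates$label, size = estimates$sizeClass,
                    nominal_mM = estimates$nominal,
                    estimated_mM = estimates$estimated, sd = estimates$sd)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a repeatability report as CSV
#'
#' Machine-readable export: raw CoV values (no ">50.0" formatting).
#'
#' @param report a [RepeatabilityReport-class].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
writeReportCSV <- function(report, path) {
  write.csv(reportTable(report), path, row.names = FALSE)
  invisible(path)
}
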