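#' @include sodiumQA-package.R
NULL

#' DigitalPhantom: a rasterized multi-vial dilution phantom
#'
#' Container for the digital version of the cylindrical-vial sodium phantom:
#' a vial registry (label, size class, nominal concentration, geometry), a
#' per-vial relaxation table, and concentration / vial-label volumes
#' rasterized on a regular grid (voxel-center sampling, phantom axis along z,
#' grid origin at the volume center).
#'
#' @slot vials data.frame with columns `label`, `sizeClass`, `concentration`
#'   (mM), `x`,`y`,`z` (centre, m), `innerDiameter` (m), `length` (m),
#'   `ax`,`ay`,`az` (unit cylinder axis).
#' @slot relaxation data.frame keyed by `label` with columns `T1`, `T2fast`,
#'   `T2slow` (s) and `fastFraction` (in `[0,1]`).
#' @slot fov numeric length-3 field of view (m).
#' @slot gridShape integer length-3 grid size.
#' @slot concentration 3D numeric array (mM); exactly 0 outside all vials.
#' @slot labelVolume 3D integer array; 0 = background, i = row i of `vials`.
#'
#' @seealso [buildPhantom()], [rasterizePhantom()], [dilutionSeries()]
#' @export
setClass("DigitalPhantom",
  representation(
    vials = "data.frame",
    relaxation = "data.frame",
    fov = "numeric",
    gridShape = "integer",
    concentration = "array",
    labelVolume = "array"
  )
)

setValidity("DigitalPhantom", function(object) {
  msg <- character()
  v <- object@vials
  need <- c("label", "sizeClass", "concentration", "x", "y", "z",
            "innerDiameter", "length", "ax", "ay", "az")
  if (!all(need %in% names(v))) {
    msg <- c(msg, paste("vial registry must have columns:",
                        paste(setdiff(need, names(v)), collapse = ", ")))
  } else {
    if (anyDuplicated(v$label)) msg <- c(msg, "vial labels must be unique")
    if (any(v$concentration < 0)) msg <- c(msg, "nominal concentrations must be >= 0")
    if (any(v$innerDiameter <= 0) || any(v$length <= 0))
      msg <- c(msg, "vial dimensions must be positive")
  }
  if (length(object@fov) != 3 || any(object@fov <= 0))
    msg <- c(msg, "fov must be 3 positive lengths")
  if (length(object@gridShape) != 3 || any(object@gridShape < 1))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (!identical(dim(object@concentration), as.integer(object@gridShape)))
    msg <- c(msg, "concentration volume dimensions must equal gridShape")
  if (any(object@concentration < 0))
    msg <- c(msg, "concentration volume must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TrajectorySet: 3D radial golden-angle sampling geometry
#'
#' Spoke directions, center-out radial sample positions, per-sample timing and
#' analytic density-compensation weights for a 3D radial golden-angle
#' acquisition. Radial positions, times and weights are shared by all spokes.
#'
#' @slot directions n_spokes x 3 matrix of unit vectors.
#' @slot kRadial radial sample positions per spoke (cycles/m), 0 to kmax.
#' @slot sampleTimes time from excitation per radial sample (s).
#' @slot kmax maximum sampled spatial frequency, `1/(2 * nominal resolution)`.
#' @slot densityWeights per-radial-sample weights (shared across spokes),
#'   normalized so that the grand total over all spokes equals the sampled
#'   k-space ball volume `4/3 pi kmax^3`.
#'
#' @seealso [buildTrajectory()], [goldenAngleDirections()], [densityWeights()]
#' @export
setClass("TrajectorySet",
  representation(
    directions = "matrix",
    kRadial = "numeric",
    sampleTimes = "numeric",
    kmax = "numeric",
    densityWeights = "numeric"
  )
)

setValidity("TrajectorySet", function(object) {
  msg <- character()
  n <- sqrt(rowSums(object@directions^2))
  if (any(abs(n - 1) > 1e-9)) msg <- c(msg, "spoke directions must be unit vectors")
  if (is.unsorted(object@kRadial, strictly = TRUE) && length(object@kRadial) > 1)
    msg <- c(msg, "radial k positions must be strictly increasing")
  if (length(object@densityWeights) != length(object@kRadial))
    msg <- c(msg, "density weights must match radial sample count")
  if (any(object@densityWeights < 0)) msg <- c(msg, "density weights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' KSpaceDataset: simulated radial k-space sessions
#'
#' Complex radial k-space samples for one simulated session, with full
#' acquisition provenance (trajectory, parameters, noise level, seed).
#'
#' @slot samples complex array `[repeat, spoke, readout sample]`.
#' @slot trajectory the [TrajectorySet-class] the samples live on.
#' @slot params acquisition parameter list from [acqParams()].
#' @slot noiseSigma per-channel (real/imaginary) Gaussian noise SD; 0 for a
#'   noiseless dataset.
#' @slot seed integer session seed (per-repeat streams are derived from it).
#' @slot sessionId character identifier.
#' @slot repeatIds character vector, one per repeat.
#'
#' @seealso [simulateKspace()], [averageRepeats()], [gridReconstruct()]
#' @export
setClass("KSpaceDataset",
  representation(
    samples = "array",
    trajectory = "TrajectorySet",
    params = "list",
    noiseSigma = "numeric",
    seed = "integer",
    sessionId = "character",
    repeatIds = "character"
  )
)

setValidity("KSpaceDataset", function(object) {
  msg <- character()
  d <- dim(object@samples)
  if (length(d) != 3) msg <- c(msg, "samples must be a 3D array [repeat, spoke, sample]")
  else {
    if (d[2] != nrow(object@trajectory@directions))
      msg <- c(msg, "spoke count must match trajectory")
    if (d[3] != length(object@trajectory@kRadial))
      msg <- c(msg, "readout sample count must match trajectory")
    if (length(object@repeatIds) != d[1])
      msg <- c(msg, "repeatIds must have one entry per repeat")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ReconImage: reconstructed 3D magnitude image
#'
#' @slot data 3D numeric magnitude array (non-negative).
#' @slot complexData complex reconstruction, or a 0-length array if dropped.
#' @slot voxelSize voxel edge lengths (m), equal to the reconstruction
#'   resolution.
#' @slot provenance list: dataset id, parameter/config hashes, alignment
#'   shifts, etc.
#'
#' @seealso [gridReconstruct()], [writeImage()], [alignTranslation()]
#' @export
setClass("ReconImage",
  representation(
    data = "array",
    complexData = "array",
    voxelSize = "numeric",
    provenance = "list"
  )
)

setValidity("ReconImage", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3) msg <- c(msg, "image data must be 3D")
  if (any(object@data < 0)) msg <- c(msg, "magnitude image must be non-negative")
  if (length(object@complexData) &&
      !identical(dim(object@complexData), dim(object@data)))
    msg <- c(msg, "complex volume must match magnitude dimensions")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths")
  if (length(msg)) msg else TRUE
})

#' ConcentrationMap: voxelwise sodium concentration estimates
#'
#' Result of applying an intensity-to-concentration calibration line to a
#' magnitude image. Negative voxel values are permitted (noise below the
#' regression intercept maps below 0 mM).
#'
#' @slot data 3D numeric array (mM).
#' @slot voxelSize voxel edge lengths (m).
#' @slot provenance list with the calibration fit and source image ids.
#'
#' @seealso [concentrationMap()], [estimateVialConcentrations()]
#' @export
setClass("ConcentrationMap",
  representation(
    data = "array",
    voxelSize = "numeric",
    provenance = "list"
  )
)

#' ROISet: circular analysis regions on the central axial slice
#'
#' One circular ROI per vial (centered on the vial axis) plus four circular
#' background noise ROIs near the corners of the field of view. ROI centers
#' are snapped to the nearest voxel center, which is always included in the
#' ROI even when the disc radius is below the voxel size.
#'
#' @slot vialROIs data.frame: `label`, `i`,`j` (1-based in-plane voxel
#'   indices), `slice` (1-based axial index), `diameter` (m), `sizeClass`,
#'   `nominal` (mM).
#' @slot noiseROIs data.frame: `label`, `i`, `j`, `slice`, `diameter`,
#'   `depth` (m; the disc is replicated over `depth` to pool more background
#'   voxels).
#' @slot slice central axial slice index (1-based).
#' @slot gridShape grid the indices refer to.
#' @slot voxelSize voxel edge lengths (m).
#'
#' @seealso [placeROIs()], [roiStatistics()], [measureSNR()]
#' @export
setClass("ROISet",
  representation(
    vialROIs = "data.frame",
    noiseROIs = "data.frame",
    slice = "integer",
    gridShape = "integer",
    voxelSize = "numeric"
  )
)

#' CalibrationFit: noise-anchored intensity-to-concentration regression
#'
#' Ordinary least-squares line `intensity = slope * concentration +
#' intercept` fitted to the four large-vial ROI means plus the pooled
#' background mean treated as a 0 mM point.
#'
#' @slot slope intensity per mM (must be positive for a valid calibration).
#' @slot intercept intensity at 0 mM.
#' @slot rSquared coefficient of determination.
#' @slot points data.frame of the calibration points (`label`,
#'   `concentration`, `intensity`).
#'
#' @seealso [fitCalibration()], [concentrationMap()]
#' @export
setClass("CalibrationFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    points = "data.frame"
  )
)

#' SessionResult: one end-to-end simulated scan session
#'
#' @slot sessionId character identifier.
#' @slot day day index (1-based).
#' @slot scan scan index within the day (1-based).
#' @slot estimates data.frame of per-vial estimated concentrations
#'   (`label`, `sizeClass`, `nominal`, `estimated`, `sd`).
#' @slot snr measured SNR (large 77 mM vial over background SD).
#' @slot seed integer session seed.
#' @slot flipAngle degrees.
#' @slot fit the session's [CalibrationFit-class].
#' @slot provenance list (noise sigma, config hash, drift factor, shifts).
#'
#' @seealso [runSession()], [repeatabilityReport()]
#' @export
setClass("SessionResult",
  representation(
    sessionId = "character",
    day = "integer",
    scan = "integer",
    estimates = "data.frame",
    snr = "numeric",
    seed = "integer",
    flipAngle = "numeric",
    fit = "CalibrationFit",
    provenance = "list"
  )
)

#' RepeatabilityReport: per-vial CoV tables for a multi-session design
#'
#' Intra-day repeatability is the coefficient of variation over the scans of
#' one session (day); inter-day repeatability is the CoV of the first scan of
#' each day. Raw CoV values are preserved; values above 50 are rendered as
#' ">50.0" only when formatting.
#'
#' @slot table data.frame: `label`, `sizeClass`, `nominal`, `mean`, `sd`,
#'   `intraCoV`, `interCoV`, `nIntra`, `nInter`.
#' @slot design list describing the session design (days, scans per day,
#'   which day anchors the intra-day CoV).
#'
#' @seealso [repeatabilityReport()], [coefficientOfVariation()]
#' @export
setClass("RepeatabilityReport",
  representation(
    table = "data.frame",
    design = "list"
  )
)
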