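#' @include AllClasses.R
NULL

#' Accessors for sodiumQA containers
#'
#' Small accessor generics used across the package: `vials()` returns the
#' vial registry of a phantom, `concentrationVolume()` its rasterized mM
#' volume, `labelVolume()` the integer vial-index volume, `imageData()` the
#' numeric payload of an image or map, `voxelSize()` the voxel edge lengths
#' in metres, `fieldOfView()` the field of view, `gridShape()` grid
#' dimensions, `kSamples()` the complex sample array of a k-space dataset,
#' and `reportTable()` the per-vial table of a repeatability report.
#'
#' @param object a sodiumQA S4 object.
#' @return The slot payload documented above.
#' @name accessors
#' @aliases vials concentrationVolume labelVolume imageData voxelSize
#'   fieldOfView gridShape kSamples reportTable
#' @examples
#' ph <- buildPhantom(phantomConfig(scale = 0.125))
#' nrow(vials(ph))
#' dim(concentrationVolume(ph))
NULL

#' @rdname accessors
#' @export
setGeneric("vials", function(object) standardGeneric("vials"))
#' @rdname accessors
#' @export
setGeneric("concentrationVolume", function(object) standardGeneric("concentrationVolume"))
#' @rdname accessors
#' @export
setGeneric("labelVolume", function(object) standardGeneric("labelVolume"))
#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("fieldOfView", function(object) standardGeneric("fieldOfView"))
#' @rdname accessors
#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("kSamples", function(object) standardGeneric("kSamples"))
#' @rdname accessors
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))

#' @rdname accessors
setMethod("vials", "DigitalPhantom", function(object) object@vials)
#' @rdname accessors
setMethod("concentrationVolume", "DigitalPhantom", function(object) object@concentration)
#' @rdname accessors
setMethod("labelVolume", "DigitalPhantom", function(object) object@labelVolume)
#' @rdname accessors
setMethod("voxelSize", "DigitalPhantom", function(object) object@fov / object@gridShape)
#' @rdname accessors
setMethod("fieldOfView", "DigitalPhantom", function(object) object@fov)
#' @rdname accessors
setMethod("gridShape", "DigitalPhantom", function(object) object@gridShape)

#' @rdname accessors
setMethod("imageData", "ReconImage", function(object) object@data)
#' @rdname accessors
setMethod("voxelSize", "ReconImage", function(object) object@voxelSize)
#' @rdname accessors
setMethod("gridShape", "ReconImage", function(object) as.integer(dim(object@data)))
#' @rdname accessors
setMethod("imageData", "ConcentrationMap", function(object) object@data)
#' @rdname accessors
setMethod("voxelSize", "ConcentrationMap", function(object) object@voxelSize)
#' @rdname accessors
setMethod("kSamples", "KSpaceDataset", function(object) object@samples)
#' @rdname accessors
setMethod("reportTable", "RepeatabilityReport", function(object) object@table)

setMethod("show", "DigitalPhantom", function(object) {
  cat(sprintf("DigitalPhantom: %d vial(s), grid %s, FOV %s cm\n",
              nrow(object@vials),
              paste(object@gridShape, collapse = "x"),
              paste(signif(object@fov * 100, 4), collapse = "x")))
  cat(sprintf("  concentrations [mM]: %s\n",
              paste(sort(unique(object@vials$concentration)), collapse = ", ")))
  cat(sprintf("  non-zero voxels: %d\n", sum(object@labelVolume > 0)))
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet: %d spokes x %d samples, kmax %.1f cycles/m\n",
              nrow(object@directions), length(object@kRadial), object@kmax))
})

setMethod("show", "KSpaceDataset", function(object) {
  d <- dim(object@samples)
  cat(sprintf("KSpaceDataset '%s': %d repeat(s) x %d spokes x %d samples\n",
              object@sessionId, d[1], d[2], d[3]))
  cat(sprintf("  noise sigma %.4g, seed %d\n", object@noiseSigma, object@seed))
})

setMethod("show", "ReconImage", function(object) {
  cat(sprintf("ReconImage: %s grid, voxel %s mm%s\n",
              paste(dim(object@data), collapse = "x"),
              paste(signif(object@voxelSize * 1e3, 4), collapse = "x"),
              if (length(object@complexData)) ", complex volume kept" else ""))
})

setMethod("show", "ConcentrationMap", function(object) {
  cat(sprintf("ConcentrationMap: %s grid, voxel %s mm, range [%.2f, %.2f] mM\n",
              paste(dim(object@data), collapse = "x"),
              paste(signif(object@voxelSize * 1e3, 4), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d vial ROI(s) + %d noise ROI(s) on slice %d\n",
              nrow(object@vialROIs), nrow(object@noiseROIs), object@slice))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit: intensity = %.4g * C[mM] + %.4g (r^2 = %.4f, %d points)\n",
              object@slope, object@intercept, object@rSquared, nrow(object@points)))
})

setMethod("show", "SessionResult", function(object) {
  cat(sprintf("SessionResult '%s' (day %d, scan %d): SNR %.1f, FA %g deg, seed %d\n",
              object@sessionId, object@day, object@scan, object@snr,
              object@flipAngle, object@seed))
})

setMethod("show", "RepeatabilityReport", function(object) {
  cat("RepeatabilityReport (CoV in %, '>50.0' formatting applied):\n")
  print(formatReport(object))
})
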