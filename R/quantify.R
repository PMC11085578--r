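#' @include recon.R
NULL

#' Automatic ROI placement on the central axial slice
#'
#' Places one circular ROI per vial, centered on the vial axis in the central
#' axial slice, with the protocol's diameters: 12 mm for large vials and
#' 8 mm for medium, small and the central reference vial. Four circular
#' background noise ROIs (diameter 22.5 mm) are placed near the corners of
#' the field of view; to pool a stable number of background voxels on coarse
#' desk-scale grids, each noise disc is replicated over an axial depth equal
#' to its diameter (a short cylinder). ROI centers snap to the nearest voxel
#' center, which is always part of the ROI.
#'
#' @param phantom a [DigitalPhantom-class] (provides vial centers and the
#'   rasterized footprints used for validation).
#' @param grid a `"ReconParams"` list, a [ReconImage-class], or an integer
#'   grid size; defines the image grid the ROI indices refer to.
#' @param fov field of view (m) when `grid` is a bare grid size.
#' @param vialDiameters named diameters (m) per size class.
#' @param noiseDiameter noise ROI diameter (m).
#' @param noiseMargin distance of noise ROI centers from the FOV edge (m).
#' @return An [ROISet-class].
#' @examples
#' ph <- buildPhantom(phantomConfig(scale = 0.25))
#' rois <- placeROIs(ph, reconParams(scale = 0.25))
#' nrow(rois@vialROIs)  # 13
#' @export
placeROIs <- function(phantom, grid = reconParams(),
                      fov = NULL,
                      vialDiameters = c(large = 12e-3, medium = 8e-3,
                                        small = 8e-3),
                      noiseDiameter = 22.5e-3,
                      noiseMargin = 0.04) {
  stopifnot(is(phantom, "DigitalPhantom"), nrow(phantom@vials) >= 1)
  if (inherits(grid, "ReconParams")) {
    n <- rep(grid$gridShape, 3); fv <- rep(grid$fov, 3)
  } else if (is(grid, "ReconImage")) {
    n <- dim(imageData(grid)); fv <- n * voxelSize(grid)
  } else {
    n <- rep(as.integer(grid), length.out = 3)
    fv <- if (is.null(fov)) phantom@fov else rep(fov, length.out = 3)
  }
  delta <- fv / n
  toIdx <- function(x, ax) as.integer(round(x / delta[ax]) + n[ax] %/% 2 + 1)
  slice <- toIdx(0, 3)
  v <- phantom@vials
  vialROIs <- data.frame(
    label = v$label, sizeClass = v$sizeClass, nominal = v$concentration,
    i = toIdx(v$x, 1), j = toIdx(v$y, 2), slice = slice,
    diameter = unname(vialDiameters[v$sizeClass]),
    stringsAsFactors = FALSE)
  if (anyNA(vialROIs$diameter)) stop("missing ROI diameter for a vial size class")
  for (r in seq_len(nrow(vialROIs)))
    if (vialROIs$diameter[r] > v$innerDiameter[r])
      stop(sprintf("ROI placement error: ROI for '%s' (%.1f mm) exceeds the vial bore (%.1f mm)",
                   v$label[r], vialROIs$diameter[r] * 1e3, v$innerDiameter[r] * 1e3))
  cornerPos <- fv[1] / 2 - noiseMargin
  corners <- expand.grid(x = c(-cornerPos, cornerPos), y = c(-cornerPos, cornerPos))
  noiseROIs <- data.frame(
    label = paste0("noise_", seq_len(4)),
    i = toIdx(corners$x, 1), j = toIdx(corners$y, 2), slice = slice,
    diameter = noiseDiameter, depth = noiseDiameter,
    stringsAsFactors = FALSE)
  rois <- new("ROISet", vialROIs = vialROIs, noiseROIs = noiseROIs,
              slice = slice, gridShape = as.integer(n), voxelSize = delta)
  # noise ROIs must not intersect any vial footprint
  ext <- max(sqrt(v$x^2 + v$y^2) + v$innerDiameter / 2)
  if (sqrt(2) * cornerPos - noiseDiameter / 2 <= ext)
    stop("ROI placement error: noise ROIs would intersect the phantom")
  rois
}

# 1-based voxel indices of a circular ROI (disc) of given diameter, centered
# on the voxel (i, j) of slice k, optionally replicated over `depth` metres.
.roiVoxelIndices <- function(i, j, slice, diameter, gridShape, delta, depth = 0) {
  rad <- diameter / 2
  ri <- ceiling(rad / delta[1]); rj <- ceiling(rad / delta[2])
  ii <- max(1, i - ri):min(gridShape[1], i + ri)
  jj <- max(1, j - rj):min(gridShape[2], j + rj)
  g <- expand.grid(i = ii, j = jj)
  keep <- ((g$i - i) * delta[1])^2 + ((g$j - j) * delta[2])^2 <= rad^2
  g <- g[keep | (g$i == i & g$j == j), , drop = FALSE]
  nz <- max(0, floor(depth / (2 * delta[3])))
  kk <- max(1, slice - nz):min(gridShape[3], slice + nz)
  out <- do.call(rbind, lapply(kk, function(k) cbind(g$i, g$j, k)))
  out
}

#' ROI statistics on a magnitude image
#'
#' Per-ROI mean, standard deviation and voxel count over the magnitude
#' image, plus one pooled row (label `".noise"`) combining the voxels of all
#' background noise ROIs.
#'
#' @param image a [ReconImage-class] (or [ConcentrationMap-class]).
#' @param rois an [ROISet-class] on the same grid.
#' @return data.frame with columns `label`, `sizeClass`, `nominal`, `mean`,
#'   `sd`, `nVoxels`; noise rows have `sizeClass = "noise"` and
#'   `nominal = 0`.
#' @export
roiStatistics <- function(image, rois) {
  stopifnot(is(rois, "ROISet"))
  arr <- imageData(image)
  if (!identical(as.integer(dim(arr)), rois@gridShape))
    stop("image grid does not match the ROI set")
  delta <- rois@voxelSize
  statRow <- function(label, sizeClass, nominal, vox) {
    if (nrow(vox) == 0) stop(sprintf("empty ROI '%s'", label))
    vals <- arr[vox]
    data.frame(label = label, sizeClass = sizeClass, nominal = nominal,
               mean = mean(vals), sd = sd(vals), nVoxels = length(vals),
               stringsAsFactors = FALSE)
  }
  vres <- do.call(rbind, lapply(seq_len(nrow(rois@vialROIs)), function(r) {
    ro <- rois@vialROIs[r, ]
    vox <- .roiVoxelIndices(ro$i, ro$j, ro$slice, ro$diameter,
                            rois@gridShape, delta)
    statRow(ro$label, ro$sizeClass, ro$nominal, vox)
  }))
  noiseVox <- do.call(rbind, lapply(seq_len(nrow(rois@noiseROIs)), function(r) {
    ro <- rois@noiseROIs[r, ]
    .roiVoxelIndices(ro$i, ro$j, ro$slice, ro$diameter, rois@gridShape,
                     delta, depth = ro$depth)
  }))
  pooled <- statRow(".noise", "noise", 0, noiseVox)
  rbind(vres, pooled)
}

#' Image SNR from ROI statistics
#'
#' SNR defined as the mean magnitude in the signal vial ROI (by default the
#' large 77 mM vial) divided by the standard deviation of the pooled
#' background magnitude voxels. No Rician correction is applied — this
#' matches the scanner-side ROI definition the protocol uses. A zero noise
#' SD (noiseless simulation) yields `Inf` with a warning.
#'
#' @inheritParams roiStatistics
#' @param signalLabel label of the signal ROI.
#' @return SNR (dimensionless), possibly `Inf`.
#' @export
measureSNR <- function(image, rois, signalLabel = "L_77") {
  tab <- roiStatistics(image, rois)
  sig <- tab$mean[tab$label == signalLabel]
  if (!length(sig)) stop(sprintf("signal ROI '%s' not found", signalLabel))
  noiseSD <- tab$sd[tab$label == ".noise"]
  if (noiseSD == 0) {
    warning("zero background SD: SNR is unbounded (noiseless image)")
    return(Inf)
  }
  sig / noiseSD
}

#' Noise-anchored linear calibration of image intensity vs concentration
#'
#' Ordinary (unweighted) least-squares fit of ROI mean intensity against
#' known sodium concentration using the four large-vial ROI means plus the
#' pooled background mean treated as a 0 mM point. Medium/small vials and
#' the central 154 mM reference are excluded from the fit and act as test
#' points (the 154 mM estimate is an extrapolation).
#'
#' @param roiTable data.frame from [roiStatistics()].
#' @param concentrations named numeric vector mapping ROI labels to known
#'   concentrations (mM). The default selects the four large vials (via
#'   their `nominal` column) and the pooled `".noise"` row at 0 mM.
#' @param noisePoint which background anchor to use: `"pooled"` (all four
#'   noise ROIs, the default) or one of the individual noise ROI labels.
#' @return A [CalibrationFit-class].
#' @export
fitCalibration <- function(roiTable, concentrations = NULL,
                           noisePoint = "pooled") {
  if (is.null(concentrations)) {
    largeRows <- roiTable[roiTable$sizeClass == "large", ]
    concentrations <- setNames(largeRows$nominal, largeRows$label)
    anchor <- if (identical(noisePoint, "pooled")) ".noise" else noisePoint
    concentrations[anchor] <- 0
  }
  rows <- roiTable[match(names(concentrations), roiTable$label), ]
  if (anyNA(rows$mean)) stop("calibration labels missing from the ROI table")
  conc <- as.numeric(concentrations)
  if (length(unique(conc)) < 2) stop("degenerate calibration: need at least 2 distinct concentrations")
  fit <- lm(rows$mean ~ conc)
  pts <- data.frame(label = names(concentrations), concentration = conc,
                    intensity = rows$mean, stringsAsFactors = FALSE)
  ssTot <- sum((rows$mean - mean(rows$mean))^2)
  r2 <- if (ssTot > 0) 1 - sum(residuals(fit)^2) / ssTot else 1
  new("CalibrationFit", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), rSquared = r2, points = pts)
}

#' Voxelwise concentration map from a calibration fit
#'
#' Inverts the calibration line voxelwise:
#' `C(v) = (intensity(v) - intercept) / slope`. Negative concentrations are
#' preserved (background voxels below the regression intercept map below
#' 0 mM).
#'
#' @param image a [ReconImage-class].
#' @param fit a [CalibrationFit-class] with non-zero slope.
#' @return A [ConcentrationMap-class].
#' @export
concentrationMap <- function(image, fit) {
  stopifnot(is(image, "ReconImage"), is(fit, "CalibrationFit"))
  if (fit@slope == 0) stop("calibration slope is zero; cannot invert")
  new("ConcentrationMap",
      data = (imageData(image) - fit@intercept) / fit@slope,
      voxelSize = voxelSize(image),
      provenance = list(fit = fit, image = image@provenance))
}

#' Per-vial estimated concentrations
#'
#' ROI-mean concentration per vial on a concentration map — the quantity the
#' repeatability analysis tracks across sessions.
#'
#' @param map a [ConcentrationMap-class].
#' @param rois an [ROISet-class].
#' @return data.frame with `label`, `sizeClass`, `nominal`, `estimated`
#'   (mM) and `sd` (ROI SD, mM).
#' @export
estimateVialConcentrations <- function(map, rois) {
  tab <- roiStatistics(map, rois)
  tab <- tab[tab$sizeClass != "noise", ]
  data.frame(label = tab$label, sizeClass = tab$sizeClass,
             nominal = tab$nominal, estimated = tab$mean, sd = tab$sd,
             stringsAsFactors = FALSE, row.names = NULL)
}
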