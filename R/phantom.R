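#' @include AllClasses.R
NULL

#' Two-fold saline dilution series
#'
#' Concentrations obtained by sequential 1:1 water dilutions of a stock
#' solution: each step exactly halves the previous concentration. Physiologic
#' saline (154 mM NaCl) diluted four times yields the phantom's vial series
#' 77, 38.5, 19.25 and 9.625 mM.
#'
#' @param stock stock concentration (mM), must be positive.
#' @param steps number of dilution steps (non-negative integer).
#' @return Numeric vector `c(stock/2, stock/4, ..., stock/2^steps)`;
#'   `numeric(0)` when `steps = 0`.
#' @examples
#' dilutionSeries(154, 4)  # 77 38.5 19.25 9.625
#' @export
dilutionSeries <- function(stock, steps) {
  if (!is.numeric(stock) || length(stock) != 1 || !is.finite(stock) || stock <= 0)
    stop("'stock' must be a single positive concentration")
  if (!is.numeric(steps) || length(steps) != 1 || steps < 0 || steps != round(steps))
    stop("'steps' must be a single non-negative integer")
  if (steps == 0) return(numeric(0))
  stock / 2^seq_len(steps)
}

#' Relaxation parameter sets
#'
#' Sodium relaxation parameters for a phantom compartment. Transverse decay is
#' bi-exponential with a fast and a slow component; `fastFraction = 0` gives a
#' mono-exponential (aqueous saline) compartment. Two presets are provided:
#' `"saline"` (mono-exponential, T2 = 50 ms, T1 = 60 ms, matching NaCl
#' solutions) and `"agarose"` (bi-exponential, T2 fast/slow = 3/25 ms, fast
#' fraction 0.6, mimicking tissue-like gel phantoms).
#'
#' @param T1 longitudinal relaxation time (s).
#' @param T2fast fast transverse component (s); must not exceed `T2slow`.
#' @param T2slow slow transverse component (s).
#' @param fastFraction fraction of the fast component, in `[0, 1]`.
#' @param preset for [relaxationPreset()]: `"saline"` or `"agarose"`.
#' @return A named list with class `"RelaxationParams"`.
#' @examples
#' relaxationPreset("saline")
#' relaxationParams(T1 = 0.06, T2fast = 0.003, T2slow = 0.025, fastFraction = 0.6)
#' @export
relaxationParams <- function(T1, T2fast, T2slow, fastFraction = 0) {
  stopifnot(T1 > 0, T2fast > 0, T2slow > 0)
  if (T2fast > T2slow) stop("'T2fast' must not exceed 'T2slow'")
  if (fastFraction < 0 || fastFraction > 1) stop("'fastFraction' must be in [0, 1]")
  structure(list(T1 = T1, T2fast = T2fast, T2slow = T2slow,
                 fastFraction = fastFraction),
            class = "RelaxationParams")
}

#' @rdname relaxationParams
#' @export
relaxationPreset <- function(preset = c("saline", "agarose")) {
  preset <- match.arg(preset)
  switch(preset,
    saline  = relaxationParams(T1 = 0.060, T2fast = 0.050, T2slow = 0.050,
                               fastFraction = 0),
    agarose = relaxationParams(T1 = 0.060, T2fast = 0.003, T2slow = 0.025,
                               fastFraction = 0.6)
  )
}

#' Configuration of the digital dilution phantom
#'
#' Describes the default phantom: twelve cylindrical vials (three sizes x
#' four concentrations from [dilutionSeries()] of 154 mM stock) evenly spaced
#' every 30 degrees on a ring, size classes interleaved so the layout is
#' mirror-symmetric about the center, plus one central small vial holding the
#' undiluted 154 mM reference. All vial axes are parallel to z; the "axial
#' slice" plane is xy. Large/medium vial dimensions default to standard
#' 50 mL / 15 mL conical-tube geometry; the small-vial dimensions are the
#' measured ones (inner diameter 1 cm, length 8.5 cm).
#'
#' `scale` uniformly shrinks the rasterization grid for desk-scale runs
#' (voxel size grows by `1/scale`); the physical phantom geometry is
#' unchanged.
#'
#' @param scale grid scale factor in (0, 1]; 1 is the full 1.5 mm grid.
#' @param fov field of view (m), scalar or length 3.
#' @param gridShape grid size per axis; default `round(256 * scale)`.
#' @param ringRadius radius of the vial ring (m).
#' @param stock stock concentration (mM).
#' @param steps number of dilution steps.
#' @param relaxation a `"RelaxationParams"` list applied to every vial
#'   (per-vial overrides may be edited on the built phantom).
#' @param sizes named list of `c(innerDiameter, length)` (m) per size class.
#' @param vials optional custom vial registry data.frame (same columns as
#'   [DigitalPhantom-class] `vials`); when supplied it replaces the default
#'   ring layout entirely.
#' @return A named list with class `"PhantomConfig"`.
#' @seealso [buildPhantom()]
#' @export
phantomConfig <- function(scale = 1,
                          fov = 0.384,
                          gridShape = NULL,
                          ringRadius = 0.05,
                          stock = 154,
                          steps = 4,
                          relaxation = relaxationPreset("saline"),
                          sizes = list(large  = c(0.028, 0.110),
                                       medium = c(0.015, 0.118),
                                       small  = c(0.010, 0.085)),
                          vials = NULL) {
  stopifnot(scale > 0, scale <= 1, all(fov > 0))
  if (length(fov) == 1) fov <- rep(fov, 3)
  if (is.null(gridShape)) gridShape <- round(256 * scale)
  if (length(gridShape) == 1) gridShape <- rep(gridShape, 3)
  structure(list(scale = scale, fov = fov, gridShape = as.integer(gridShape),
                 ringRadius = ringRadius, stock = stock, steps = steps,
                 relaxation = relaxation, sizes = sizes, vials = vials),
            class = "PhantomConfig")
}

.defaultVialRegistry <- function(config) {
  conc <- dilutionSeries(config$stock, config$steps)  # high to low
  sizeCycle <- c("large", "medium", "small")
  rows <- lapply(0:11, function(i) {
    size <- sizeCycle[i %% 3 + 1]
    cc <- conc[i %/% 3 + 1]
    ang <- i * (2 * pi / 12)
    dims <- config$sizes[[size]]
    data.frame(
      label = paste0(toupper(substr(size, 1, 1)), "_", format(cc, trim = TRUE)),
      sizeClass = size, concentration = cc,
      x = config$ringRadius * cos(ang), y = config$ringRadius * sin(ang), z = 0,
      innerDiameter = dims[1], length = dims[2],
      ax = 0, ay = 0, az = 1,
      stringsAsFactors = FALSE)
  })
  dims <- config$sizes[["small"]]
  centre <- data.frame(
    label = paste0("Centre_", format(config$stock, trim = TRUE)),
    sizeClass = "small", concentration = config$stock,
    x = 0, y = 0, z = 0,
    innerDiameter = dims[1], length = dims[2],
    ax = 0, ay = 0, az = 1,
    stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(centre)))
}

# Analytic overlap test for parallel-axis (z-aligned) cylinder pairs.
.checkVialOverlap <- function(v) {
  zAligned <- abs(v$az - 1) < 1e-12 & abs(v$ax) < 1e-12 & abs(v$ay) < 1e-12
  n <- nrow(v)
  if (n < 2) return(invisible(TRUE))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (!(zAligned[a] && zAligned[b])) next
    d <- sqrt((v$x[a] - v$x[b])^2 + (v$y[a] - v$y[b])^2)
    rsum <- (v$innerDiameter[a] + v$innerDiameter[b]) / 2
    zOverlap <- abs(v$z[a] - v$z[b]) < (v$length[a] + v$length[b]) / 2
    if (d < rsum && zOverlap)
      stop(sprintf("vial layout error: '%s' and '%s' overlap (centre distance %.1f mm < %.1f mm)",
                   v$label[a], v$label[b], d * 1e3, rsum * 1e3))
  }
  invisible(TRUE)
}

# Voxel-centre coordinates along one axis: index a (1-based) maps to
# (a - 1 - floor(n/2)) * delta, so x = 0 lies on a voxel centre.
.axisCoords <- function(n, delta) (seq_len(n) - 1 - floor(n / 2)) * delta

.rasterizeRegistry <- function(v, gridShape, fov) {
  delta <- fov / gridShape
  if (nrow(v) && min(delta) > min(v$innerDiameter) / 2)
    warning("voxel size exceeds the smallest vial radius; thin vials may rasterize poorly")
  xs <- .axisCoords(gridShape[1], delta[1])
  ys <- .axisCoords(gridShape[2], delta[2])
  zs <- .axisCoords(gridShape[3], delta[3])
  lab <- array(0L, dim = gridShape)
  conc <- array(0, dim = gridShape)
  for (i in seq_len(nrow(v))) {
    r <- v$innerDiameter[i] / 2
    halfLen <- v$length[i] / 2
    if (abs(v$az[i] - 1) < 1e-12 && abs(v$ax[i]) < 1e-12 && abs(v$ay[i]) < 1e-12) {
      inPlane <- outer((xs - v$x[i])^2, (ys - v$y[i])^2, "+") <= r^2
      zIdx <- which(abs(zs - v$z[i]) <= halfLen)
      if (!any(inPlane) || !length(zIdx)) next
      ij <- which(inPlane, arr.ind = TRUE)
      for (k in zIdx) {
        lab[cbind(ij, k)] <- i
        conc[cbind(ij, k)] <- v$concentration[i]
      }
    } else {
      a <- c(v$ax[i], v$ay[i], v$az[i])
      for (k in seq_along(zs)) {
        dx <- outer(xs - v$x[i], rep(1, length(ys)))
        dy <- outer(rep(1, length(xs)), ys - v$y[i])
        dz <- zs[k] - v$z[i]
        t <- dx * a[1] + dy * a[2] + dz * a[3]
        rad2 <- dx^2 + dy^2 + dz^2 - t^2
        m <- rad2 <= r^2 & abs(t) <= halfLen
        if (any(m)) {
          ij <- which(m, arr.ind = TRUE)
          lab[cbind(ij, k)] <- i
          conc[cbind(ij, k)] <- v$concentration[i]
        }
      }
    }
  }
  list(label = lab, concentration = conc)
}

#' Build the digital dilution phantom
#'
#' Assembles the vial registry described by a [phantomConfig()] (or a custom
#' registry supplied in the config), verifies that no two vials overlap, and
#' rasterizes concentration and vial-label volumes on the configured grid.
#' The construction is fully deterministic.
#'
#' @param config a `"PhantomConfig"` from [phantomConfig()].
#' @return A [DigitalPhantom-class].
#' @examples
#' ph <- buildPhantom(phantomConfig(scale = 0.125))
#' nrow(vials(ph))  # 13
#' @export
buildPhantom <- function(config = phantomConfig()) {
  if (!inherits(config, "PhantomConfig")) stop("'config' must come from phantomConfig()")
  v <- if (is.null(config$vials)) .defaultVialRegistry(config) else config$vials
  if (anyDuplicated(v$label)) stop("vial labels must be unique")
  .checkVialOverlap(v)
  relax <- data.frame(label = v$label,
                      T1 = rep(config$relaxation$T1, nrow(v)),
                      T2fast = rep(config$relaxation$T2fast, nrow(v)),
                      T2slow = rep(config$relaxation$T2slow, nrow(v)),
                      fastFraction = rep(config$relaxation$fastFraction, nrow(v)),
                      stringsAsFactors = FALSE)
  ras <- .rasterizeRegistry(v, config$gridShape, config$fov)
  for (i in seq_len(nrow(v)))
    if (!any(ras$label == i))
      warning(sprintf("vial '%s' rasterized to zero voxels at this grid resolution", v$label[i]))
  new("DigitalPhantom", vials = v, relaxation = relax,
      fov = config$fov, gridShape = as.integer(config$gridShape),
      concentration = ras$concentration, labelVolume = ras$label)
}

#' Re-rasterize a phantom on a different grid
#'
#' Rasterizes the vial registry of an existing phantom on a new grid. A voxel
#' belongs to a vial iff its center lies inside the vial cylinder, so the
#' voxel-count volume of each vial converges to the analytic cylinder volume
#' as the voxel size shrinks.
#'
#' @param phantom a [DigitalPhantom-class].
#' @param gridShape new grid size (scalar or length 3).
#' @param fov new field of view (m); defaults to the phantom's.
#' @return A new [DigitalPhantom-class] on the requested grid.
#' @export
rasterizePhantom <- function(phantom, gridShape, fov = fieldOfView(phantom)) {
  stopifnot(is(phantom, "DigitalPhantom"))
  if (length(gridShape) == 1) gridShape <- rep(gridShape, 3)
  if (length(fov) == 1) fov <- rep(fov, 3)
  ras <- .rasterizeRegistry(phantom@vials, as.integer(gridShape), fov)
  new("DigitalPhantom", vials = phantom@vials, relaxation = phantom@relaxation,
      fov = fov, gridShape = as.integer(gridShape),
      concentration = ras$concentration, labelVolume = ras$label)
}

# Per-vial voxel coordinates (metres) and amplitudes on the phantom grid;
# the simulator's voxel basis. Returns only non-background voxels.
.phantomVoxels <- function(phantom) {
  idx <- which(phantom@labelVolume > 0, arr.ind = TRUE)
  delta <- voxelSize(phantom)
  coords <- cbind(.axisCoords(phantom@gridShape[1], delta[1])[idx[, 1]],
                  .axisCoords(phantom@gridShape[2], delta[2])[idx[, 2]],
                  .axisCoords(phantom@gridShape[3], delta[3])[idx[, 3]])
  list(coords = coords,
       vial = phantom@labelVolume[idx],
       concentration = phantom@concentration[idx],
       voxelVolume = prod(delta))
}
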