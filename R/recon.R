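#' @include acquisition.R
NULL

#' Reconstruction parameters
#'
#' Gridding (adjoint NUFFT) reconstruction settings. The reconstruction grid
#' is `round(fov / reconResolution)` per axis; the Kaiser-Bessel
#' interpolation kernel has finite support `kernelWidth` (in oversampled grid
#' cells) on a grid oversampled by `gridOversampling`, with the shape
#' parameter beta set by the standard minimum-aliasing prescription.
#' `scale` coarsens the reconstructed resolution by `1/scale` for desk-scale
#' runs (full scale reconstructs at 1.5 mm).
#'
#' @param reconResolution reconstructed voxel size (m).
#' @param gridOversampling k-space grid oversampling factor (>= 1).
#' @param kernelWidth kernel support in oversampled grid cells.
#' @param fov field of view (m).
#' @param scale desk-scale factor in (0, 1].
#' @return Named list with class `"ReconParams"` (includes the derived grid
#'   shape `gridShape` and kernel `beta`).
#' @seealso [gridReconstruct()]
#' @export
reconParams <- function(reconResolution = 1.5e-3,
                        gridOversampling = 2,
                        kernelWidth = 4,
                        fov = 0.384,
                        scale = 1) {
  stopifnot(scale > 0, scale <= 1, gridOversampling >= 1, kernelWidth >= 2)
  reconResolution <- reconResolution / scale
  n <- as.integer(round(fov / reconResolution))
  g <- as.integer(2 * ceiling(n * gridOversampling / 2))
  osEff <- g / n
  beta <- pi * sqrt(kernelWidth^2 / osEff^2 * (osEff - 0.5)^2 - 0.8)
  structure(list(reconResolution = reconResolution,
                 gridOversampling = gridOversampling,
                 kernelWidth = kernelWidth, fov = fov, scale = scale,
                 gridShape = n, oversampledShape = g, beta = beta),
            class = "ReconParams")
}

.defaultReconParams <- function(scale = 1) reconParams(scale = scale)

# Analytic 3D radial density weights for one spoke: proportional to k^2 with
# the k = 0 sample given the k^2-equivalent of the central Nyquist cell
# (equating 4 pi k^2 dk shell volume with the central sphere of radius dk/2
# gives k^2 -> dk^2 / 24). Normalized so the grand total over all spokes
# equals the sampled k-space ball volume 4/3 pi kmax^3.
.radialDensityWeights <- function(kRadial, nSpokes, kmax = max(kRadial)) {
  dk <- if (length(kRadial) > 1) kRadial[2] - kRadial[1] else kmax
  raw <- kRadial^2
  raw[kRadial == 0] <- dk^2 / 24
  vol <- 4 / 3 * pi * kmax^3
  raw * vol / (nSpokes * sum(raw))
}

#' Density-compensation weights of a radial trajectory
#'
#' Per-radial-sample analytic weights proportional to `k^2` (the 3D radial
#' sampling density correction), with the `k = 0` sample assigned the volume
#' of the central Nyquist cell, normalized so that the total over all spokes
#' equals the sampled k-space ball volume. The same radial weight vector
#' applies to every spoke.
#'
#' @param trajectory a [TrajectorySet-class].
#' @return Numeric vector of per-radial-sample weights (length =
#'   samples per spoke).
#' @export
densityWeights <- function(trajectory) {
  stopifnot(is(trajectory, "TrajectorySet"))
  .radialDensityWeights(trajectory@kRadial, nrow(trajectory@directions),
                        trajectory@kmax)
}

#' Average the repeats of a k-space dataset
#'
#' Complex mean across repeats; the noise SD of the average is
#' `sigma / sqrt(n)` and is recorded as such on the returned dataset.
#'
#' @param dataset a [KSpaceDataset-class] with at least one repeat.
#' @return A [KSpaceDataset-class] with a single repeat.
#' @export
averageRepeats <- function(dataset) {
  stopifnot(is(dataset, "KSpaceDataset"))
  d <- dim(dataset@samples)
  if (d[1] == 1) return(dataset)
  avg <- array(colMeans(dataset@samples), dim = c(1, d[2], d[3]))
  new("KSpaceDataset", samples = avg, trajectory = dataset@trajectory,
      params = dataset@params, noiseSigma = dataset@noiseSigma / sqrt(d[1]),
      seed = dataset@seed, sessionId = dataset@sessionId,
      repeatIds = paste0(dataset@sessionId, "_avg"))
}

# Continuous Fourier transform of the (unnormalized) Kaiser-Bessel kernel
# I0(beta sqrt(1 - (2 kappa / W)^2)) on |kappa| <= W/2, evaluated at image
# coordinate t (cycles per grid cell): W sinh(g)/g with
# g = sqrt(beta^2 - (pi W t)^2) (sin for imaginary g). Used for
# deapodization.
.kbTransform <- function(t, width, beta) {
  g2 <- beta^2 - (pi * width * t)^2
  out <- numeric(length(g2))
  pos <- g2 > 0
  out[pos] <- width * sinh(sqrt(g2[pos])) / sqrt(g2[pos])
  gn <- sqrt(-g2[!pos])
  out[!pos] <- width * ifelse(gn == 0, 1, sin(gn) / gn)
  out
}

.fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  x[idx[[1]], idx[[2]], idx[[3]]]
}

#' Gridding (adjoint NUFFT) reconstruction of a radial dataset
#'
#' Density-compensated adjoint non-uniform Fourier transform: samples are
#' weighted by the analytic radial density compensation, convolved onto an
#' oversampled Cartesian grid with a Kaiser-Bessel kernel, inverse-FFT'd,
#' deapodized and cropped to the reconstruction grid. The output is the
#' magnitude image (the complex volume can be kept). With
#' `method = "dft"` the adjoint is instead evaluated as an exact non-uniform
#' DFT sum — identical contract, no kernel approximation — which is only
#' practical on small grids and serves as the reference path.
#'
#' Datasets with several repeats are averaged internally (recorded in the
#' image provenance).
#'
#' @param dataset a [KSpaceDataset-class].
#' @param params a `"ReconParams"` list; its FOV must match the acquisition.
#' @param method `"gridding"` (default) or `"dft"` (exact adjoint sum).
#' @param applyWeights apply density compensation (default TRUE).
#' @param keepComplex keep the complex volume alongside the magnitude.
#' @return A [ReconImage-class] on the `params$gridShape` grid.
#' @examples
#' ph <- buildPhantom(phantomConfig(scale = 0.125))
#' p <- acqParams(scale = 0.125, nAverages = 1)
#' ds <- simulateKspace(ph, params = p, noiseSigma = 0, seed = 1L)
#' img <- gridReconstruct(ds, reconParams(scale = 0.125))
#' @export
gridReconstruct <- function(dataset, params = reconParams(),
                            method = c("gridding", "dft"),
                            applyWeights = TRUE, keepComplex = FALSE) {
  method <- match.arg(method)
  stopifnot(is(dataset, "KSpaceDataset"))
  if (!isTRUE(all.equal(params$fov, dataset@params$fov)))
    stop("configuration error: reconstruction FOV does not match acquisition FOV")
  averaged <- dim(dataset@samples)[1] > 1
  if (averaged) dataset <- averageRepeats(dataset)
  tr <- dataset@trajectory
  nR <- length(tr@kRadial)
  y <- as.vector(dataset@samples[1, , ])  # [spoke, sample] flattened spoke-fastest
  if (applyWeights) {
    w <- densityWeights(tr)
    y <- y * rep(w, each = nrow(tr@directions))
  }
  k <- .kCoordinates(tr)
  n <- params$gridShape
  cplx <- if (method == "dft") {
    coords <- as.matrix(expand.grid(
      .axisCoords(n, params$fov / n), .axisCoords(n, params$fov / n),
      .axisCoords(n, params$fov / n)))
    array(cppNudftAdjoint(k, as.complex(y), coords), dim = rep(n, 3))
  } else {
    g <- params$oversampledShape
    u <- k * params$fov * (g / n)
    grid <- array(cppKbSpread(u, as.complex(y), g, params$kernelWidth,
                              params$beta), dim = rep(g, 3))
    img <- .fftshift3(fft(grid, inverse = TRUE))
    ctr <- g / 2 + 1
    keep <- (ctr - n %/% 2):(ctr + n - n %/% 2 - 1)
    img <- img[keep, keep, keep]
    m <- (seq_len(n) - 1 - n %/% 2) / g
    de <- .kbTransform(m, params$kernelWidth, params$beta)
    img / outer(outer(de, de), de)
  }
  mag <- Mod(cplx)
  new("ReconImage", data = mag,
      complexData = if (keepComplex) cplx else array(complex(0), dim = c(0, 0, 0)),
      voxelSize = rep(params$fov / n, 3),
      provenance = list(sessionId = dataset@sessionId, seed = dataset@seed,
                        method = method, applyWeights = applyWeights,
                        averagedInternally = averaged,
                        reconParams = unclass(params)))
}

#' Integer-voxel translation alignment by circular cross-correlation
#'
#' Finds the integer-voxel shift of `moving` that maximizes the circular
#' cross-correlation of the two magnitude volumes (computed by FFT), applies
#' it as a circular shift, and reports a confidence flag: when the
#' correlation peak barely exceeds the runner-up (peak ratio below
#' `threshold`, as happens for pure-noise inputs) the result is flagged
#' low-confidence.
#'
#' @param moving,reference [ReconImage-class] objects on the same grid.
#' @param threshold peak-ratio threshold for the low-confidence flag.
#' @return List with `shift` (integer length 3), `aligned` (shifted
#'   [ReconImage-class]), `peakRatio`, and `lowConfidence` (logical).
#' @export
alignTranslation <- function(moving, reference, threshold = 1.05) {
  stopifnot(is(moving, "ReconImage"), is(reference, "ReconImage"))
  a <- imageData(reference); b <- imageData(moving)
  if (!identical(dim(a), dim(b))) stop("images must share a grid shape")
  d <- dim(a)
  cc <- Re(fft(Conj(fft(b)) * fft(a), inverse = TRUE))
  peak <- which.max(cc)
  pk <- arrayInd(peak, d)
  lag <- as.integer(pk) - 1L
  lag <- ifelse(lag > d / 2, lag - d, lag)
  # the correlation peaks at lag = -t when moving is reference displaced by t
  shift <- as.integer(-lag)
  # runner-up outside the immediate neighborhood of the peak
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbIdx <- t((t(nb) + as.integer(pk) - 1L) %% d + 1L)
  ccMasked <- cc
  ccMasked[nbIdx] <- -Inf
  peakRatio <- cc[peak] / max(ccMasked)
  aligned <- .circularShift(b, -shift)
  img <- new("ReconImage", data = aligned, complexData = moving@complexData,
             voxelSize = moving@voxelSize,
             provenance = c(moving@provenance, list(alignmentShift = shift)))
  list(shift = shift, aligned = img, peakRatio = peakRatio,
       lowConfidence = !is.finite(peakRatio) || peakRatio < threshold)
}

# Shift an array circularly so that aligned[x] = x[x - shift] (i.e. the
# content moves by +shift).
.circularShift <- function(x, shift) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(ax) ((seq_len(d[ax]) - 1 - shift[ax]) %% d[ax]) + 1)
  x[idx[[1]], idx[[2]], idx[[3]]]
}
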