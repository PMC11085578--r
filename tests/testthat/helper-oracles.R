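# Independent brute-force oracles. These deliberately avoid the package's
# compiled code paths: plain R loops / closed forms only.

# Exact non-uniform DFT, S_j = sum_v a_v exp(-2 pi i k_j . x_v)
oracleForwardDFT <- function(coords, amp, k) {
  vapply(seq_len(nrow(k)), function(j) {
    ph <- -2 * pi * (k[j, 1] * coords[, 1] + k[j, 2] * coords[, 2] +
                       k[j, 3] * coords[, 3])
    sum(amp * complex(modulus = 1, argument = ph))
  }, complex(1))
}

# Exact adjoint sum, I_v = sum_j y_j exp(+2 pi i k_j . x_v)
oracleAdjointDFT <- function(k, y, coords) {
  vapply(seq_len(nrow(coords)), function(v) {
    ph <- 2 * pi * (k[, 1] * coords[v, 1] + k[, 2] * coords[v, 2] +
                      k[, 3] * coords[v, 3])
    sum(y * complex(modulus = 1, argument = ph))
  }, complex(1))
}

# Closed-form ordinary least squares for y ~ a + b x
oracleOLS <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = a, slope = b, r2 = r2)
}

# Voxel-loop ROI mean/SD over an index matrix
oracleROIStats <- function(arr, vox) {
  vals <- numeric(nrow(vox))
  for (r in seq_len(nrow(vox))) vals[r] <- arr[vox[r, 1], vox[r, 2], vox[r, 3]]
  list(mean = sum(vals) / length(vals),
       sd = sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)))
}

# A small off-centre single-vial phantom on a coarse grid, cheap enough for
# brute-force DFT comparisons.
tinyPhantom <- function(grid = 16L, fov = 0.16,
                        centre = c(0.02, -0.015, 0.01),
                        diameter = 0.05, len = 0.06, conc = 50) {
  reg <- data.frame(label = "V_50", sizeClass = "small", concentration = conc,
                    x = centre[1], y = centre[2], z = centre[3],
                    innerDiameter = diameter, length = len,
                    ax = 0, ay = 0, az = 1, stringsAsFactors = FALSE)
  cfg <- phantomConfig(fov = fov, gridShape = grid, vials = reg)
  suppressWarnings(buildPhantom(cfg))
}

tinyAcq <- function(nSpokes = 24, fov = 0.16, res = 0.02, nAvg = 1) {
  acqParams(fov = fov, nominalResolution = res, nSpokes = nSpokes,
            oversampling = 2, nAverages = nAvg)
}

buildDefaultPhantom <- function(scale) {
  suppressWarnings(buildPhantom(phantomConfig(scale = scale)))
}
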