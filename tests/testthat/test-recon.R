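test_that("radial density weights follow the k-squared law and normalization", {
  p <- tinyAcq(nSpokes = 16)
  tr <- buildTrajectory(p)
  w <- densityWeights(tr)
  k <- tr@kRadial
  # pure k^2 ratio away from the centre: samples at k and 2k weigh 1:4
  expect_equal(w[5] / w[3], (k[5] / k[3])^2, tolerance = 1e-12)
  expect_gt(w[1], 0)
  # grand total over all spokes equals the sampled k-space ball volume
  expect_equal(sum(w) * nrow(tr@directions), 4 / 3 * pi * tr@kmax^3,
               tolerance = 1e-10)
})

test_that("repeat averaging reduces noise as 1/sqrt(n) and is exact for identical repeats", {
  ph <- tinyPhantom()
  p <- tinyAcq(nSpokes = 8, nAvg = 3)
  z <- simulateKspace(ph, params = p, noiseSigma = 0, seed = 1L)
  avg <- averageRepeats(z)
  expect_identical(dim(kSamples(avg))[1], 1L)
  expect_equal(kSamples(avg)[1, , ], kSamples(z)[1, , ], tolerance = 1e-15)
  # single repeat: identity
  one <- simulateKspace(ph, params = tinyAcq(nSpokes = 8, nAvg = 1),
                        noiseSigma = 0, seed = 1L)
  expect_identical(averageRepeats(one), one)
  # 12 noise-only repeats: SD of the average ~ sigma / sqrt(12)
  ph0 <- tinyPhantom(conc = 0)
  p12 <- acqParams(fov = 0.16, nominalResolution = 0.005, nSpokes = 60,
                   nAverages = 12)
  ns <- simulateKspace(ph0, params = p12, noiseSigma = 1, seed = 5L)
  avg12 <- averageRepeats(ns)
  vals <- c(Re(kSamples(avg12)), Im(kSamples(avg12)))
  expect_gt(length(vals), 3e3)
  expect_equal(sd(vals), 1 / sqrt(12), tolerance = 0.1)
  expect_equal(avg12@noiseSigma, 1 / sqrt(12), tolerance = 1e-12)
})

test_that("gridding reconstruction matches the brute-force adjoint DFT oracle", {
  ph <- tinyPhantom()
  p <- tinyAcq(nSpokes = 64)
  tr <- buildTrajectory(p)
  ds <- simulateKspace(ph, tr, p, noiseSigma = 0, seed = 1L)
  rp <- reconParams(reconResolution = 0.01, fov = 0.16)  # 16^3 recon grid
  n <- rp$gridShape
  expect_identical(n, 16L)

  y <- as.vector(kSamples(ds)[1, , ]) * rep(densityWeights(tr), each = p$nSpokes)
  k <- sodiumQA:::.kCoordinates(tr)
  ax <- sodiumQA:::.axisCoords(n, rp$fov / n)
  coords <- as.matrix(expand.grid(ax, ax, ax))
  expected <- array(oracleAdjointDFT(k, y, coords), dim = rep(n, 3))

  # exact-DFT path agrees with the oracle essentially to machine precision
  imgD <- gridReconstruct(ds, rp, method = "dft", keepComplex = TRUE)
  expect_lt(max(Mod(imgD@complexData - expected)) / max(Mod(expected)), 1e-10)

  # Kaiser-Bessel gridding approximates it to below 1e-3 normalized RMS
  imgG <- gridReconstruct(ds, rp, method = "gridding", keepComplex = TRUE)
  nrmsd <- sqrt(mean(Mod(imgG@complexData - expected)^2)) /
    sqrt(mean(Mod(expected)^2))
  expect_lt(nrmsd, 1e-3)
  expect_equal(imgG@data, Mod(imgG@complexData), tolerance = 1e-15)
  expect_equal(unname(imgG@voxelSize[1]), rp$fov / n, tolerance = 1e-15)
})

test_that("forward simulator and reconstruction adjoint satisfy the inner-product identity", {
  ph <- tinyPhantom(grid = 12L)
  p <- tinyAcq(nSpokes = 20)
  tr <- buildTrajectory(p)
  # A maps voxel concentrations to k-space (decay off): a scalar multiple of
  # the pure DFT, with the scalar c = voxelVolume * flash
  Ax <- simulateNoiselessSignal(ph, tr, p, decay = "none")
  vox <- sodiumQA:::.phantomVoxels(ph)
  cScal <- vox$voxelVolume * flashSteadyState(p$flipAngle, p$TR, ph@relaxation$T1[1])

  set.seed(3)
  nS <- p$nSpokes; nR <- length(tr@kRadial)
  y <- matrix(complex(real = rnorm(nS * nR), imaginary = rnorm(nS * nR)), nS, nR)
  ds <- new("KSpaceDataset", samples = array(y, dim = c(1, nS, nR)),
            trajectory = tr, params = unclass(p), noiseSigma = 0, seed = 1L,
            sessionId = "adjtest", repeatIds = "adjtest_rep01")
  rp <- reconParams(reconResolution = 0.16 / 12, fov = 0.16)
  expect_identical(rp$gridShape, 12L)
  adj <- gridReconstruct(ds, rp, method = "dft", applyWeights = FALSE,
                         keepComplex = TRUE)
  # restrict <x, A^H y> to the phantom support (x is zero elsewhere)
  xAtSupport <- vox$concentration
  adjAtSupport <- adj@complexData[labelVolume(ph) > 0]
  lhs <- sum(Conj(Ax) * y)
  rhs <- cScal * sum(Conj(xAtSupport) * adjAtSupport)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
})

test_that("reconstruction is linear and maps zero data to a zero image", {
  ph <- tinyPhantom()
  p <- tinyAcq(nSpokes = 16)
  tr <- buildTrajectory(p)
  rp <- reconParams(reconResolution = 0.01, fov = 0.16)
  mk <- function(y) new("KSpaceDataset", samples = array(y, dim = c(1, dim(y))),
                        trajectory = tr, params = unclass(p), noiseSigma = 0,
                        seed = 1L, sessionId = "lin", repeatIds = "lin_rep01")
  nS <- p$nSpokes; nR <- length(tr@kRadial)
  zero <- gridReconstruct(mk(matrix(complex(real = 0), nS, nR)), rp)
  expect_true(all(imageData(zero) == 0))

  set.seed(9)
  y1 <- matrix(complex(real = rnorm(nS * nR), imaginary = rnorm(nS * nR)), nS, nR)
  y2 <- matrix(complex(real = rnorm(nS * nR), imaginary = rnorm(nS * nR)), nS, nR)
  a <- 2.5 - 1.25i; b <- -0.7 + 0.3i
  r1 <- gridReconstruct(mk(y1), rp, keepComplex = TRUE)@complexData
  r2 <- gridReconstruct(mk(y2), rp, keepComplex = TRUE)@complexData
  r12 <- gridReconstruct(mk(a * y1 + b * y2), rp, keepComplex = TRUE)@complexData
  expect_equal(r12, a * r1 + b * r2, tolerance = 1e-10)
})

test_that("point source at the phantom centre reconstructs with its maximum at the centre voxel", {
  ph <- tinyPhantom(grid = 16L, centre = c(0, 0, 0), diameter = 0.012,
                    len = 0.012)
  p <- tinyAcq(nSpokes = 200)
  ds <- simulateKspace(ph, params = p, noiseSigma = 0, seed = 1L)
  rp <- reconParams(reconResolution = 0.01, fov = 0.16)
  img <- gridReconstruct(ds, rp)
  peak <- arrayInd(which.max(imageData(img)), dim(imageData(img)))
  expect_equal(as.vector(peak), rep(9, 3))  # centre voxel of the 16-grid
})

test_that("translation alignment recovers known integer shifts and flags noise", {
  ph <- tinyPhantom()
  p <- tinyAcq(nSpokes = 64)
  ds <- simulateKspace(ph, params = p, noiseSigma = 0, seed = 1L)
  rp <- reconParams(reconResolution = 0.01, fov = 0.16)
  ref <- gridReconstruct(ds, rp)

  same <- alignTranslation(ref, ref)
  expect_identical(same$shift, c(0L, 0L, 0L))
  expect_false(same$lowConfidence)

  shifted <- new("ReconImage",
                 data = sodiumQA:::.circularShift(imageData(ref), c(2L, -1L, 0L)),
                 complexData = array(complex(0), dim = c(0, 0, 0)),
                 voxelSize = ref@voxelSize, provenance = list())
  al <- alignTranslation(shifted, ref)
  expect_identical(al$shift, c(2L, -1L, 0L))
  expect_equal(imageData(al$aligned), imageData(ref), tolerance = 1e-12)

  set.seed(21)
  mkNoise <- function() new("ReconImage",
                            data = array(abs(rnorm(16^3)), dim = rep(16, 3)),
                            complexData = array(complex(0), dim = c(0, 0, 0)),
                            voxelSize = ref@voxelSize, provenance = list())
  noisy <- alignTranslation(mkNoise(), mkNoise())
  expect_true(noisy$lowConfidence)
})
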