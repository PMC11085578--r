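test_that("golden-angle directions are unit vectors covering the sphere near-uniformly", {
  d1 <- goldenAngleDirections(1)
  expect_equal(as.vector(d1), c(0, 0, 1))
  expect_error(goldenAngleDirections(0), ">= 1")

  d <- goldenAngleDirections(1000)
  expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-9))
  # any hemisphere holds close to half the spokes
  set.seed(7)
  for (i in 1:5) {
    normal <- rnorm(3); normal <- normal / sqrt(sum(normal^2))
    inHemi <- sum(d %*% normal > 0)
    expect_gte(inHemi, 400)
    expect_lte(inHemi, 600)
  }
  # full protocol: the mean direction nearly vanishes
  dm <- colMeans(goldenAngleDirections(15460))
  expect_lt(sqrt(sum(dm^2)), 0.05)
})

test_that("trajectory geometry follows the protocol arithmetic", {
  p <- acqParams()
  tr <- buildTrajectory(p)
  expect_equal(tr@kmax, 1 / (2 * 1.86e-3), tolerance = 1e-12)   # 268.8 cycles/m
  expect_identical(length(tr@kRadial), as.integer(ceiling(tr@kmax * 0.384) * 2))
  # centre-out UTE: first sample of every spoke at k = 0, t = TE
  expect_identical(tr@kRadial[1], 0)
  expect_identical(tr@sampleTimes[1], p$TE)
  expect_true(all(diff(tr@kRadial) > 0))
  # halving the nominal resolution doubles kmax
  tr2 <- buildTrajectory(acqParams(nominalResolution = 1.86e-3 / 2))
  expect_equal(tr2@kmax, 2 * tr@kmax, tolerance = 1e-12)
})

test_that("FLASH steady state has the textbook limits and optimum", {
  expect_equal(flashSteadyState(90, TR = 10, T1 = 0.06), 1, tolerance = 1e-6)
  expect_identical(flashSteadyState(0, TR = 0.005, T1 = 0.06), 0)
  best <- optimize(function(a) flashSteadyState(a, 0.005, 0.060),
                   c(1, 89), maximum = TRUE)$maximum
  expect_equal(best, 23.1, tolerance = 0.1)
})

test_that("bi-exponential transverse decay evaluates its closed form", {
  sal <- relaxationPreset("saline")
  expect_identical(transverseDecay(0, sal), 1)
  expect_equal(transverseDecay(sal$T2slow, sal), exp(-1), tolerance = 1e-12)
  ag <- relaxationParams(T1 = 0.06, T2fast = 0.003, T2slow = 0.025,
                         fastFraction = 0.6)
  expect_equal(transverseDecay(0.003, ag),
               0.6 * exp(-1) + 0.4 * exp(-3 / 25), tolerance = 1e-12)
})

test_that("forward simulator matches the brute-force DFT oracle per time segment", {
  ph <- tinyPhantom()
  p <- tinyAcq(nSpokes = 24)
  tr <- buildTrajectory(p)
  sig <- simulateNoiselessSignal(ph, tr, p)

  vox <- sodiumQA:::.phantomVoxels(ph)
  relax <- ph@relaxation
  flash <- flashSteadyState(p$flipAngle, p$TR, relax$T1)
  baseAmp <- vox$concentration * vox$voxelVolume * flash[vox$vial]
  segs <- sodiumQA:::.readoutSegments(length(tr@kRadial), p$nSegments)
  for (seg in segs) {
    tMid <- mean(tr@sampleTimes[seg])
    dec <- vapply(seq_len(nrow(relax)), function(i)
      transverseDecay(tMid, as.list(relax[i, ])), numeric(1))
    amp <- baseAmp * dec[vox$vial]
    k <- sodiumQA:::.kCoordinates(tr, seg)
    expected <- oracleForwardDFT(vox$coords, amp, k)
    got <- as.vector(sig[, seg])
    expect_lt(max(Mod(got - expected)) / max(Mod(expected)), 1e-10)
  }
})

test_that("forward model obeys DC value, scaling, and conjugate symmetry", {
  ph <- tinyPhantom()
  p <- tinyAcq(nSpokes = 8)
  tr <- buildTrajectory(p)
  # DC sample equals the voxel-volume-weighted amplitude sum (decay off)
  sig <- simulateNoiselessSignal(ph, tr, p, decay = "none")
  vox <- sodiumQA:::.phantomVoxels(ph)
  flash <- flashSteadyState(p$flipAngle, p$TR, ph@relaxation$T1[1])
  expect_equal(Re(sig[1, 1]), sum(vox$concentration) * vox$voxelVolume * flash,
               tolerance = 1e-10)
  expect_equal(Im(sig[1, 1]), 0, tolerance = 1e-12)

  # doubling all concentrations doubles every noiseless sample exactly
  ph2 <- tinyPhantom(conc = 100)
  sig2 <- simulateNoiselessSignal(ph2, tr, p, decay = "none")
  expect_equal(sig2, 2 * sig, tolerance = 1e-12)

  # paired +/- directions: S(-k) = conj(S(k)) for a real-valued image
  dirs <- goldenAngleDirections(6)
  trPM <- new("TrajectorySet", directions = rbind(dirs, -dirs),
              kRadial = tr@kRadial, sampleTimes = tr@sampleTimes,
              kmax = tr@kmax, densityWeights = tr@densityWeights)
  sigPM <- simulateNoiselessSignal(ph, trPM, p, decay = "none")
  expect_equal(sigPM[7:12, ], Conj(sigPM[1:6, ]), tolerance = 1e-12)

  # zero-concentration phantom gives exactly zero samples
  ph0 <- tinyPhantom(conc = 0)
  expect_true(all(simulateNoiselessSignal(ph0, tr, p) == 0))
})

test_that("k-space sessions are deterministic in the seed and record provenance", {
  ph <- tinyPhantom()
  p <- tinyAcq(nSpokes = 8, nAvg = 3)
  a <- simulateKspace(ph, params = p, noiseSigma = 1e-6, seed = 11L)
  b <- simulateKspace(ph, params = p, noiseSigma = 1e-6, seed = 11L)
  expect_identical(kSamples(a), kSamples(b))
  c <- simulateKspace(ph, params = p, noiseSigma = 1e-6, seed = 12L)
  expect_false(identical(kSamples(a), kSamples(c)))
  expect_identical(a@seed, 11L)
  expect_identical(dim(kSamples(a))[1], 3L)
  # repeats carry independent noise
  expect_false(identical(kSamples(a)[1, , ], kSamples(a)[2, , ]))
  # noiseless dataset records sigma = 0
  z <- simulateKspace(ph, params = p, noiseSigma = 0, seed = 11L)
  expect_identical(z@noiseSigma, 0)
  expect_identical(kSamples(z)[1, , ], kSamples(z)[2, , ])
})

test_that("acquisition parameter invariants are enforced", {
  expect_error(acqParams(TE = 6e-3), "TE must be smaller")
  expect_error(acqParams(flipAngle = 0), "flipAngle")
  expect_error(acqParams(flipAngle = 180), "flipAngle")
  p <- acqParams(scale = 0.25)
  expect_identical(p$nSpokes, as.integer(round(15460 * 0.25)))
  expect_equal(p$nominalResolution, 1.86e-3 / 0.25, tolerance = 1e-12)
})
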