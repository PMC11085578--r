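# Shared desk-scale (scale 0.25) experiment, computed once per test run and
# reused across test files: noise calibration to the protocol's SNR-79
# regime, the 3 scans/day x 3 day session design, and one noiseless session.

.deskCache <- new.env(parent = emptyenv())

deskConfig <- function() {
  if (is.null(.deskCache$config)) .deskCache$config <- runConfig(scale = 0.25)
  .deskCache$config
}

deskPhantom <- function() {
  if (is.null(.deskCache$phantom))
    .deskCache$phantom <- buildDefaultPhantom(0.25)
  .deskCache$phantom
}

deskSigma <- function() {
  if (is.null(.deskCache$sigma)) {
    cfg <- deskConfig()
    .deskCache$sigma <- calibrateNoiseSigma(
      deskPhantom(), cfg$acq, targetSnr = cfg$targetSnr,
      reconParams = cfg$recon, seed = 101L)
  }
  .deskCache$sigma
}

deskSessions <- function() {
  if (is.null(.deskCache$sessions)) {
    cfg <- deskConfig()
    cfg$noiseSigma <- as.numeric(deskSigma())
    .deskCache$sessions <- suppressWarnings(
      runRepeatabilityExperiment(cfg, days = 3, scansPerDay = 3, baseSeed = 1L))
  }
  .deskCache$sessions
}

# smaller (scale 0.125) fixtures for quick pipeline-level tests
smallConfig <- function() {
  if (is.null(.deskCache$smallConfig))
    .deskCache$smallConfig <- runConfig(scale = 0.125)
  .deskCache$smallConfig
}

smallPhantom <- function() {
  if (is.null(.deskCache$smallPhantom))
    .deskCache$smallPhantom <- buildDefaultPhantom(0.125)
  .deskCache$smallPhantom
}

smallNoiselessImage <- function() {
  if (is.null(.deskCache$smallImage)) {
    cfg <- smallConfig()
    ds <- simulateKspace(smallPhantom(), params = cfg$acq, noiseSigma = 0,
                         seed = 1L, nAverages = 1)
    .deskCache$smallImage <- gridReconstruct(ds, cfg$recon)
  }
  .deskCache$smallImage
}

deskSigmaSmall <- function() {
  if (is.null(.deskCache$smallSigma)) {
    cfg <- smallConfig()
    .deskCache$smallSigma <- calibrateNoiseSigma(
      smallPhantom(), cfg$acq, targetSnr = cfg$targetSnr,
      reconParams = cfg$recon, seed = 102L)
  }
  .deskCache$smallSigma
}

deskNoiselessSession <- function() {
  if (is.null(.deskCache$noiseless)) {
    cfg <- deskConfig()
    .deskCache$noiseless <- suppressWarnings(
      runSession(cfg, seed = 1L, phantom = deskPhantom(), sigma = 0))
  }
  .deskCache$noiseless
}
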