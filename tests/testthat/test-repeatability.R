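test_that("coefficient of variation matches its closed form and is scale-invariant", {
  expect_identical(coefficientOfVariation(c(10, 10, 10)), 0)
  expect_equal(coefficientOfVariation(c(9, 10, 11)), 10, tolerance = 1e-12)
  expect_equal(coefficientOfVariation(c(1, 2)),
               100 * (sqrt(2) / 2) / 1.5, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(6, mean = 20, sd = 3)
    expect_equal(coefficientOfVariation(3.7 * x), coefficientOfVariation(x),
                 tolerance = 1e-10)
  }
  expect_warning(na <- coefficientOfVariation(c(-1, 1)), "mean is zero")
  expect_identical(na, NA_real_)
  expect_warning(coefficientOfVariation(c(-3, -4)), "negative mean")
  expect_error(coefficientOfVariation(5), "at least two")
})

test_that("sessions are bit-reproducible from (config, seed)", {
  cfg <- smallConfig()
  ph <- smallPhantom()
  a <- runSession(cfg, seed = 42L, phantom = ph, sigma = 2e-4)
  b <- runSession(cfg, seed = 42L, phantom = ph, sigma = 2e-4)
  expect_identical(a@estimates, b@estimates)
  expect_identical(a@snr, b@snr)
  c <- runSession(cfg, seed = 43L, phantom = ph, sigma = 2e-4)
  expect_false(identical(a@estimates$estimated, c@estimates$estimated))
})

test_that("repeatability report computes CoV tables and validates the design", {
  mkSession <- function(day, scan, est) {
    new("SessionResult", sessionId = sprintf("d%ds%d", day, scan),
        day = as.integer(day), scan = as.integer(scan),
        estimates = data.frame(label = c("L_77", "S_9.625"),
                               sizeClass = c("large", "small"),
                               nominal = c(77, 9.625),
                               estimated = est, sd = 0),
        snr = 79, seed = 1L, flipAngle = 30,
        fit = new("CalibrationFit", slope = 1, intercept = 0, rSquared = 1,
                  points = data.frame()),
        provenance = list())
  }
  # identical sessions: every CoV is exactly zero
  same <- unlist(lapply(1:3, function(d) lapply(1:3, function(s)
    mkSession(d, s, c(75, 8)))), recursive = FALSE)
  repSame <- repeatabilityReport(same)
  expect_true(all(reportTable(repSame)$intraCoV == 0))
  expect_true(all(reportTable(repSame)$interCoV == 0))

  # hand-computable design: day-1 scans vary, first scans vary across days
  vals <- list(c(70, 8), c(77, 8), c(84, 8),   # day 1
               c(70, 9), c(70, 9), c(70, 9),   # day 2
               c(90, 7), c(90, 7), c(90, 7))   # day 3
  sess <- list(); i <- 1
  for (d in 1:3) for (s in 1:3) { sess[[i]] <- mkSession(d, s, vals[[i]]); i <- i + 1 }
  rep2 <- repeatabilityReport(sess)
  tab <- reportTable(rep2)
  expect_equal(tab$intraCoV[tab$label == "L_77"],
               100 * sd(c(70, 77, 84)) / mean(c(70, 77, 84)), tolerance = 1e-12)
  expect_equal(tab$interCoV[tab$label == "L_77"],
               100 * sd(c(70, 70, 90)) / mean(c(70, 70, 90)), tolerance = 1e-12)

  # exported CSV recomputes to the same values
  csv <- tempfile(fileext = ".csv")
  writeReportCSV(rep2, csv)
  back <- read.csv(csv)
  expect_equal(back$intraCoV, tab$intraCoV, tolerance = 1e-12)

  # ">50.0" is a formatting rule only
  big <- repeatabilityReport(list(mkSession(1, 1, c(1, 1)),
                                  mkSession(1, 2, c(4, 1)),
                                  mkSession(1, 3, c(12, 1))))
  expect_gt(reportTable(big)$intraCoV[1], 50)
  expect_identical(formatReport(big)$intraCoV[1], ">50.0")

  # missing first scans are a design error
  broken <- sess[c(1:3, 5, 6)]
  expect_error(repeatabilityReport(broken), "design error")
})

test_that("intra-day CoV of the large 77 mM vial shrinks as the noise shrinks", {
  cfg <- smallConfig()
  ph <- smallPhantom()
  tr <- buildTrajectory(cfg$acq)
  sig <- simulateNoiselessSignal(ph, tr, cfg$acq)
  rois <- placeROIs(ph, cfg$recon)
  sigmas <- max(Mod(sig)) * c(2e-2, 5e-3, 1.25e-3)
  meanCov <- vapply(sigmas, function(sg) {
    covs <- vapply(1:3, function(rep) {
      sess <- lapply(1:3, function(s)
        runSession(cfg, seed = as.integer(1000 * rep + s), phantom = ph,
                   trajectory = tr, signal = sig, rois = rois, sigma = sg,
                   day = 1L, scan = s))
      tab <- reportTable(repeatabilityReport(sess))
      tab$intraCoV[tab$label == "L_77"]
    }, numeric(1))
    mean(covs)
  }, numeric(1))
  expect_true(all(diff(meanCov) < 0))
})

test_that("flip-angle sweep tracks the FLASH steady state and picks a near-Ernst angle", {
  cfg <- smallConfig()
  ph <- smallPhantom()
  rois <- placeROIs(ph, cfg$recon)
  # noiseless amplitude ratios equal the steady-state ratios within 1%
  roiMean <- function(fa) {
    cfgFA <- cfg; cfgFA$acq$flipAngle <- fa
    ds <- simulateKspace(ph, params = cfgFA$acq, noiseSigma = 0, seed = 1L,
                         nAverages = 1)
    img <- gridReconstruct(ds, cfgFA$recon)
    tab <- roiStatistics(img, rois)
    tab$mean[tab$label == "L_77"]
  }
  m15 <- roiMean(15); m30 <- roiMean(30)
  f15 <- flashSteadyState(15, cfg$acq$TR, 0.060)
  f30 <- flashSteadyState(30, cfg$acq$TR, 0.060)
  expect_equal(m30 / m15, f30 / f15, tolerance = 0.01)

  # paired (same-seed) noisy sweep: best angle brackets the 23.1 deg optimum,
  # and the 30 deg acquisition beats both 15 and 50 deg
  sigma <- as.numeric(deskSigmaSmall())
  fa <- suppressWarnings(
    faCalibration(cfg, flipAngles = c(10, 15, 20, 30, 40, 50), seed = 7L,
                  sigma = sigma))
  expect_true(fa$bestFA %in% c(20, 30))
  snr <- setNames(fa$table$snr, fa$table$flipAngle)
  expect_gt(snr[["30"]], snr[["15"]])
  expect_gt(snr[["30"]], snr[["50"]])
})
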