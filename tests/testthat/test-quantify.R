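test_that("automatic ROI placement yields 13 vial ROIs plus 4 noise ROIs", {
  ph <- deskPhantom()
  rois <- placeROIs(ph, reconParams(scale = 0.25))
  expect_identical(nrow(rois@vialROIs), 13L)
  expect_identical(nrow(rois@noiseROIs), 4L)
  expect_identical(sum(rois@vialROIs$diameter == 12e-3), 4L)  # large vials
  expect_identical(sum(rois@vialROIs$diameter == 8e-3), 9L)   # the others

  single <- tinyPhantom()
  rois1 <- placeROIs(single, grid = 32L, fov = 0.16,
                     vialDiameters = c(small = 8e-3), noiseMargin = 0.02)
  expect_identical(nrow(rois1@vialROIs), 1L)
})

test_that("large-vial ROI voxel count approximates the analytic disc area", {
  ph <- deskPhantom()
  rois <- placeROIs(ph, reconParams(scale = 1))  # 1.5 mm voxels
  delta <- rois@voxelSize
  ro <- rois@vialROIs[rois@vialROIs$sizeClass == "large", ][1, ]
  vox <- sodiumQA:::.roiVoxelIndices(ro$i, ro$j, ro$slice, ro$diameter,
                                     rois@gridShape, delta)
  r <- ro$diameter / 2
  lo <- pi * (r - delta[1])^2 / prod(delta[1:2])
  hi <- pi * (r + delta[1])^2 / prod(delta[1:2])
  expect_gte(nrow(vox), floor(lo))
  expect_lte(nrow(vox), ceiling(hi))
})

test_that("ROI statistics match a brute-force voxel loop and handle constants", {
  ph <- deskPhantom()
  rp <- reconParams(scale = 0.25)
  rois <- placeROIs(ph, rp)
  n <- rp$gridShape
  mkImage <- function(arr) new("ReconImage", data = arr,
                               complexData = array(complex(0), dim = c(0, 0, 0)),
                               voxelSize = rep(rp$fov / n, 3),
                               provenance = list())
  # constant image: every ROI mean is the constant, SD is zero
  tabC <- roiStatistics(mkImage(array(3.5, dim = rep(n, 3))), rois)
  expect_true(all(tabC$mean == 3.5))
  expect_true(all(tabC$sd[tabC$nVoxels > 1] == 0))

  set.seed(14)
  arr <- array(abs(rnorm(n^3)), dim = rep(n, 3))
  tab <- roiStatistics(mkImage(arr), rois)
  for (r in seq_len(nrow(rois@vialROIs))) {
    ro <- rois@vialROIs[r, ]
    vox <- sodiumQA:::.roiVoxelIndices(ro$i, ro$j, ro$slice, ro$diameter,
                                       rois@gridShape, rois@voxelSize)
    expected <- oracleROIStats(arr, vox)
    row <- tab[tab$label == ro$label, ]
    expect_identical(row$mean, expected$mean)
    expect_identical(row$nVoxels, nrow(vox))
  }
  # SNR is invariant to global intensity scaling
  snr1 <- measureSNR(mkImage(arr), rois)
  snr10 <- measureSNR(mkImage(arr * 10), rois)
  expect_equal(snr10, snr1, tolerance = 1e-12)
  # zero background SD flags an unbounded SNR
  expect_warning(inf <- measureSNR(mkImage(array(1, dim = rep(n, 3))), rois),
                 "unbounded")
  expect_identical(inf, Inf)
})

test_that("calibration fit reproduces exact lines and the closed-form OLS oracle", {
  conc <- c(77, 38.5, 19.25, 9.625, 0)
  tab <- data.frame(label = c("L_77", "L_38.5", "L_19.25", "L_9.625", ".noise"),
                    sizeClass = c(rep("large", 4), "noise"),
                    nominal = conc, mean = 2 * conc + 5, sd = 0, nVoxels = 10)
  fit <- fitCalibration(tab)
  expect_equal(fit@slope, 2, tolerance = 1e-12)
  expect_equal(fit@intercept, 5, tolerance = 1e-12)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)

  # noisy toy table against the closed-form oracle
  set.seed(2)
  tab$mean <- 1.7 * conc + 3 + rnorm(5)
  fit2 <- fitCalibration(tab)
  oracle <- oracleOLS(conc, tab$mean)
  expect_equal(fit2@slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit2@intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(fit2@rSquared, oracle$r2, tolerance = 1e-12)

  # permutation invariance
  perm <- tab[c(3, 1, 5, 2, 4), ]
  fit3 <- fitCalibration(perm)
  expect_equal(fit3@slope, fit2@slope, tolerance = 1e-12)
  expect_equal(fit3@intercept, fit2@intercept, tolerance = 1e-12)

  # fewer than two distinct concentrations is degenerate
  bad <- tab[1:2, ]; bad$nominal <- 77
  expect_error(fitCalibration(bad, c(L_77 = 77, L_38.5 = 77)), "degenerate")
})

test_that("concentration maps invert the fitted line and preserve negatives", {
  fit <- new("CalibrationFit", slope = 2, intercept = 5, rSquared = 1,
             points = data.frame())
  arr <- array(5, dim = c(4, 4, 4))
  img <- new("ReconImage", data = arr,
             complexData = array(complex(0), dim = c(0, 0, 0)),
             voxelSize = rep(1e-3, 3), provenance = list())
  m <- concentrationMap(img, fit)
  expect_true(all(imageData(m) == 0))

  arr2 <- arr; arr2[1, 1, 1] <- 1   # below the intercept -> negative mM
  img2 <- new("ReconImage", data = arr2, complexData = img@complexData,
              voxelSize = img@voxelSize, provenance = list())
  m2 <- concentrationMap(img2, fit)
  expect_equal(imageData(m2)[1, 1, 1], -2, tolerance = 1e-12)

  bad <- new("CalibrationFit", slope = 0, intercept = 5, rSquared = 1,
             points = data.frame())
  expect_error(concentrationMap(img, bad), "slope")
})

test_that("estimated concentrations are invariant to global intensity scaling", {
  ph <- smallPhantom()
  cfg <- smallConfig()
  rois <- placeROIs(ph, cfg$recon)
  img <- smallNoiselessImage()
  est <- function(image) {
    tab <- roiStatistics(image, rois)
    fit <- fitCalibration(tab)
    estimateVialConcentrations(concentrationMap(image, fit), rois)$estimated
  }
  scaled <- new("ReconImage", data = imageData(img) * 4.2,
                complexData = img@complexData, voxelSize = img@voxelSize,
                provenance = img@provenance)
  expect_equal(est(scaled), est(img), tolerance = 1e-9)
})

test_that("regression self-consistency recovers the calibration concentrations", {
  res <- deskNoiselessSession()
  fit <- res@fit
  # applying the map to the calibration intensities reproduces the line
  back <- (fit@points$intensity - fit@intercept) / fit@slope
  resid <- back - fit@points$concentration
  expect_lt(max(abs(resid)), 0.05 * max(fit@points$concentration))
})
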