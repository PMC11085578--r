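#' @include quantify.R config.R
NULL

#' Coefficient of variation (percent)
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation and the raw (signed) mean: a negative mean yields a negative
#' CoV and a warning, and a zero mean yields `NA` with a warning (undefined
#' CoV). The CoV is the repeatability metric of the protocol.
#'
#' @param values numeric vector, length >= 2.
#' @return CoV in percent (scale-invariant: `CoV(c * x) = CoV(x)` for
#'   `c > 0`).
#' @examples
#' coefficientOfVariation(c(9, 10, 11))  # 10
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2) stop("CoV needs at least two values")
  m <- mean(values)
  if (m == 0) {
    warning("undefined CoV: mean is zero")
    return(NA_real_)
  }
  if (m < 0) warning("negative mean: CoV sign follows the raw mean")
  100 * sd(values) / m
}

#' Run one end-to-end simulated session
#'
#' Composes the full pipeline for a single scan: simulate the radial k-space
#' session (optionally reusing a precomputed noiseless signal), average the
#' repeats, reconstruct by gridding, optionally align to a reference image,
#' fit the noise-anchored calibration, and estimate per-vial concentrations
#' and SNR. Deterministic given (config, seed).
#'
#' @param config a `"RunConfig"` list from [runConfig()] (or [loadConfig()]).
#' @param seed integer session seed.
#' @param phantom,trajectory,signal,rois optional precomputed stage inputs,
#'   reused across sessions by the repeatability driver.
#' @param sigma per-channel k-space noise SD; when `NULL` it is taken from
#'   `config$noiseSigma` (which must then be set).
#' @param day,scan design indices stored on the result.
#' @param intensityScale global multiplicative intensity factor applied to
#'   the k-space data (models inter-day scanner drift; logged).
#' @param reference optional [ReconImage-class] to align to (translation
#'   only).
#' @return A [SessionResult-class].
#' @seealso [runRepeatabilityExperiment()], [repeatabilityReport()]
#' @export
runSession <- function(config, seed, phantom = NULL, trajectory = NULL,
                       signal = NULL, rois = NULL, sigma = NULL,
                       day = 1L, scan = 1L, intensityScale = 1,
                       reference = NULL) {
  if (is.null(phantom)) phantom <- buildPhantom(config$phantom)
  if (is.null(trajectory)) trajectory <- buildTrajectory(config$acq)
  if (is.null(signal))
    signal <- simulateNoiselessSignal(phantom, trajectory, config$acq)
  if (is.null(rois)) rois <- placeROIs(phantom, config$recon)
  if (is.null(sigma)) sigma <- config$noiseSigma
  if (is.null(sigma)) stop("no noise sigma: set config$noiseSigma or pass 'sigma'")
  id <- sprintf("day%02d_scan%02d_seed%d", day, scan, seed)
  ds <- simulateKspace(phantom, trajectory, config$acq, noiseSigma = sigma,
                       seed = seed, signal = signal, sessionId = id)
  if (intensityScale != 1) ds@samples <- ds@samples * intensityScale
  img <- gridReconstruct(averageRepeats(ds), config$recon)
  shift <- c(0L, 0L, 0L)
  if (!is.null(reference)) {
    al <- alignTranslation(img, reference)
    img <- al$aligned
    shift <- al$shift
  }
  tab <- roiStatistics(img, rois)
  snr <- measureSNR(img, rois)
  fit <- fitCalibration(tab)
  est <- estimateVialConcentrations(concentrationMap(img, fit), rois)
  new("SessionResult", sessionId = id, day = as.integer(day),
      scan = as.integer(scan), estimates = est, snr = snr,
      seed = as.integer(seed), flipAngle = config$acq$flipAngle, fit = fit,
      provenance = list(noiseSigma = as.numeric(sigma),
                        intensityScale = intensityScale,
                        alignmentShift = shift,
                        configHash = configHash(config)))
}

#' Run a multi-day repeatability experiment
#'
#' Simulates the full `days x scansPerDay` session design. Session seeds are
#' `baseSeed, baseSeed + 1, ...` in (day, scan) order. The noiseless signal,
#' trajectory and ROI set are computed once and shared — sessions differ by
#' their noise realization, an optional per-day global intensity drift
#' (default within 2%, drawn deterministically per day), and an optional
#' per-day integer-voxel shift which is corrected by translation alignment
#' to the first session's image. All injected effects are logged in each
#' session's provenance.
#'
#' @inheritParams runSession
#' @param days,scansPerDay design size (defaults 3 x 3).
#' @param baseSeed seed of the first session.
#' @param driftRange half-width of the uniform per-day intensity drift
#'   (0 disables it); day 1 has no drift.
#' @return List of [SessionResult-class] objects.
#' @export
runRepeatabilityExperiment <- function(config, days = 3, scansPerDay = 3,
                                       baseSeed = 1L, sigma = NULL,
                                       driftRange = 0.02) {
  phantom <- buildPhantom(config$phantom)
  trajectory <- buildTrajectory(config$acq)
  signal <- simulateNoiselessSignal(phantom, trajectory, config$acq)
  rois <- placeROIs(phantom, config$recon)
  if (is.null(sigma)) sigma <- config$noiseSigma
  if (is.null(sigma)) stop("no noise sigma: set config$noiseSigma or pass 'sigma'")
  set.seed(as.integer(baseSeed))
  drift <- c(1, 1 + runif(max(0, days - 1), -driftRange, driftRange))
  sessions <- vector("list", days * scansPerDay)
  idx <- 1L
  for (d in seq_len(days)) for (s in seq_len(scansPerDay)) {
    sessions[[idx]] <- runSession(config, seed = as.integer(baseSeed + idx - 1L),
                                  phantom = phantom, trajectory = trajectory,
                                  signal = signal, rois = rois, sigma = sigma,
                                  day = d, scan = s,
                                  intensityScale = drift[d])
    idx <- idx + 1L
  }
  sessions
}

.estimatesMatrix <- function(sessions) {
  labels <- sessions[[1]]@estimates$label
  vapply(sessions, function(s) {
    stopifnot(identical(s@estimates$label, labels))
    s@estimates$estimated
  }, numeric(length(labels)))
}

#' Intra-/inter-day repeatability report
#'
#' Computes, per vial, the mean and SD of the estimated concentration over
#' all sessions, the intra-day CoV (over the `scansPerDay` scans of the
#' anchor day, n = scans of one session) and the inter-day CoV (over the
#' first scan of each day, n = days). Pure function of the session results:
#' no simulation is re-run.
#'
#' @param sessions list of [SessionResult-class] from the same design.
#' @param intraDay which day anchors the intra-day CoV (default day 1).
#' @return A [RepeatabilityReport-class]; raw CoV values are kept in the
#'   table, the ">50.0" rendering is applied only by [formatReport()].
#' @export
repeatabilityReport <- function(sessions, intraDay = 1L) {
  days <- vapply(sessions, function(s) s@day, integer(1))
  scans <- vapply(sessions, function(s) s@scan, integer(1))
  if (!any(days == intraDay))
    stop(sprintf("design error: no sessions for intra-day anchor day %d", intraDay))
  missingFirst <- setdiff(unique(days), days[scans == 1])
  if (length(missingFirst))
    stop(sprintf("design error: missing first scan for day(s) %s",
                 paste(missingFirst, collapse = ", ")))
  est <- .estimatesMatrix(sessions)
  ref <- sessions[[1]]@estimates
  intra <- est[, days == intraDay, drop = FALSE]
  inter <- est[, scans == 1, drop = FALSE][, order(days[scans == 1]), drop = FALSE]
  suppress <- function(x) {
    if (length(x) < 2) return(NA_real_)   # degenerate design: CoV undefined
    suppressWarnings(coefficientOfVariation(x))
  }
  tab <- data.frame(
    label = ref$label, sizeClass = ref$sizeClass, nominal = ref$nominal,
    mean = rowMeans(est), sd = apply(est, 1, sd),
    intraCoV = apply(intra, 1, suppress),
    interCoV = apply(inter, 1, suppress),
    nIntra = ncol(intra), nInter = ncol(inter),
    stringsAsFactors = FALSE)
  new("RepeatabilityReport", table = tab,
      design = list(days = length(unique(days)),
                    scansPerDay = max(scans), intraDay = as.integer(intraDay),
                    nSessions = length(sessions)))
}

#' Format a repeatability report for display
#'
#' Applies the table rendering rule: CoV values above 50% are shown as
#' ">50.0", all others with one decimal. Raw values remain available in
#' `reportTable()`.
#'
#' @param report a [RepeatabilityReport-class].
#' @return data.frame with formatted CoV columns.
#' @export
formatReport <- function(report) {
  fmt <- function(x) ifelse(is.na(x), "NA",
                            ifelse(x > 50, ">50.0", sprintf("%.1f", x)))
  tab <- reportTable(report)
  data.frame(label = tab$label, nominal = tab$nominal,
             mean = sprintf("%.1f", tab$mean), sd = sprintf("%.2f", tab$sd),
             intraCoV = fmt(tab$intraCoV), interCoV = fmt(tab$interCoV),
             stringsAsFactors = FALSE)
}

#' Flip-angle calibration sweep
#'
#' Simulates one session per flip angle at a fixed seed (identical noise
#' realization across angles, so the comparison is paired) and reports the
#' measured SNR per angle and the angle with the best SNR. With T1 = 60 ms
#' and TR = 5 ms the FLASH steady state peaks near 23 degrees, so of the
#' nominal sweep 10-50 degrees the 20 or 30 degree acquisition wins.
#'
#' @inheritParams runSession
#' @param flipAngles flip angles to sweep (degrees), at least 2 (a single
#'   angle is returned as best trivially).
#' @return List with `table` (data.frame `flipAngle`, `snr`) and `bestFA`.
#' @export
faCalibration <- function(config, flipAngles = c(10, 20, 30, 40, 50),
                          seed = 1L, sigma = NULL) {
  phantom <- buildPhantom(config$phantom)
  trajectory <- buildTrajectory(config$acq)
  rois <- placeROIs(phantom, config$recon)
  if (is.null(sigma)) sigma <- config$noiseSigma
  if (is.null(sigma)) stop("no noise sigma: set config$noiseSigma or pass 'sigma'")
  snr <- vapply(flipAngles, function(fa) {
    cfg <- config
    cfg$acq$flipAngle <- fa
    res <- runSession(cfg, seed = seed, phantom = phantom,
                      trajectory = trajectory, rois = rois, sigma = sigma)
    res@snr
  }, numeric(1))
  tab <- data.frame(flipAngle = flipAngles, snr = snr)
  list(table = tab, bestFA = flipAngles[which.max(snr)])
}
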