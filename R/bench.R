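#' @include sodiumQA-package.R
NULL

#' Perturbing-sphere coil sensitivity
#'
#' Bench-test estimate of RF-coil sensitivity (transmit field per square
#' root of input power, \eqn{\eta = B_1/\sqrt{P}}) from the resonance shift
#' caused by a small metallic sphere placed at the (zero electric field)
#' center of the coil:
#' \deqn{\eta = c_{pol} \sqrt{ \mu_0 (f_1^2 - f_0^2) / (\pi^2 B_w r_s^3 f_0^2) }}
#' with \eqn{c_{pol} = 1/2} for a linearly polarized coil and
#' \eqn{1/\sqrt{2}} for quadrature drive (the power splits over the two
#' channels, so quadrature sensitivity is \eqn{\sqrt{2}} times the linear
#' value for the same inputs). When the coil ports were left open during the
#' bandwidth measurement (`portsOpen = TRUE`), the measured -3 dB bandwidth
#' is doubled before use. All quantities in SI units (Hz, m); the result is
#' in T per sqrt(W). The exact grouping of the \eqn{\pi^2} and bandwidth
#' factors under the root is fixed here by dimensional analysis
#' (\eqn{\eta^2} must carry \eqn{T^2 s / J}).
#'
#' @param f0 unperturbed resonance frequency (Hz).
#' @param f1 perturbed resonance frequency (Hz); must satisfy `f1 >= f0`
#'   (a metallic sphere raises the resonance).
#' @param bandwidth measured -3 dB bandwidth (Hz), positive.
#' @param sphereRadius sphere radius (m), positive.
#' @param polarization `"linear"` or `"quadrature"`.
#' @param portsOpen was the bandwidth measured with open input ports?
#' @return List with class `"CoilSensitivityResult"`: `eta` (T W^-1/2),
#'   the inputs, the polarization factor and effective bandwidth used.
#' @examples
#' perturbingSphereSensitivity(33.78e6, 33.781e6, bandwidth = 33.78e6 / 291,
#'                             sphereRadius = 11.5e-3,
#'                             polarization = "quadrature", portsOpen = TRUE)
#' @export
perturbingSphereSensitivity <- function(f0, f1, bandwidth, sphereRadius,
                                        polarization = c("linear", "quadrature"),
                                        portsOpen = FALSE) {
  polarization <- match.arg(polarization)
  if (f1 < f0) stop("measurement-order error: f1 must be >= f0 (sphere raises the resonance)")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (sphereRadius <= 0) stop("sphere radius must be positive")
  bwEff <- if (portsOpen) 2 * bandwidth else bandwidth
  cPol <- if (polarization == "quadrature") 1 / sqrt(2) else 1 / 2
  eta <- cPol * sqrt(.MU0 * (f1^2 - f0^2) / (pi^2 * bwEff * sphereRadius^3 * f0^2))
  structure(list(eta = eta, f0 = f0, f1 = f1, bandwidth = bandwidth,
                 effectiveBandwidth = bwEff, sphereRadius = sphereRadius,
                 polarization = polarization, portsOpen = portsOpen,
                 polarizationFactor = cPol),
            class = "CoilSensitivityResult")
}

#' @export
print.CoilSensitivityResult <- function(x, ...) {
  cat(sprintf("Coil sensitivity eta = %.4g T/sqrt(W) (%.4g uT/sqrt(W))\n",
              x$eta, x$eta * 1e6))
  cat(sprintf("  %s polarization (c = %.4f), Bw_eff = %.4g Hz%s, r_s = %.1f mm\n",
              x$polarization, x$polarizationFactor, x$effectiveBandwidth,
              if (x$portsOpen) " (open ports: 2x measured)" else "",
              x$sphereRadius * 1e3))
  invisible(x)
}

#' Summarize a bench measurement log
#'
#' Reads a CSV of repeated perturbing-sphere measurements (columns `f0`,
#' `f1`, `bandwidth`, `radius`, optional `polarization` and `ports_open`),
#' computes the sensitivity for each row and returns per-row values plus the
#' mean and standard deviation — the bench protocol averages several
#' repeated measurements.
#'
#' @param path CSV file path.
#' @return List with `measurements` (data.frame including an `eta` column),
#'   `mean` and `sd` of eta.
#' @export
readSensitivityLog <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("f0", "f1", "bandwidth", "radius")
  if (!all(need %in% names(tab)))
    stop(paste("measurement log must have columns:", paste(need, collapse = ", ")))
  if (is.null(tab$polarization)) tab$polarization <- "linear"
  if (is.null(tab$ports_open)) tab$ports_open <- FALSE
  tab$eta <- vapply(seq_len(nrow(tab)), function(i)
    perturbingSphereSensitivity(tab$f0[i], tab$f1[i], tab$bandwidth[i],
                                tab$radius[i], tab$polarization[i],
                                as.logical(tab$ports_open[i]))$eta,
    numeric(1))
  list(measurements = tab, mean = mean(tab$eta), sd = sd(tab$eta))
}

#' Resonator quality factor
#'
#' `Q = f0 / bandwidth` (resonance frequency over -3 dB bandwidth), the
#' standard proxy for coil losses.
#'
#' @param f0 resonance frequency (Hz).
#' @param bandwidth -3 dB bandwidth (Hz), positive.
#' @return Dimensionless Q.
#' @examples
#' qualityFactor(33.78e6, 33.78e6 / 291)  # 291
#' @export
qualityFactor <- function(f0, bandwidth) {
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  f0 / bandwidth
}

#' Larmor frequency
#'
#' `gamma * B0`. Sodium's gyromagnetic ratio is 11.26 MHz/T, about a quarter
#' of the proton's 42.57 MHz/T, which is why a 3 T sodium coil resonates at
#' 33.78 MHz.
#'
#' @param gamma gyromagnetic ratio (MHz/T).
#' @param B0 static field (T), positive.
#' @return Frequency in MHz.
#' @examples
#' larmorFrequency(11.26, 3)  # 33.78
#' @export
larmorFrequency <- function(gamma, B0) {
  if (any(B0 <= 0)) stop("B0 must be positive")
  gamma * B0
}

#' Ernst angle
#'
#' The flip angle maximizing the spoiled gradient-echo steady-state signal:
#' `acos(exp(-TR/T1))`, in degrees. Agrees with the numerical argmax of
#' [flashSteadyState()] by construction; for T1 = 60 ms and TR = 5 ms the
#' closed form gives 23.1 degrees.
#'
#' @param T1 longitudinal relaxation time (s), positive.
#' @param TR repetition time (s), positive.
#' @return Angle in degrees.
#' @examples
#' ernstAngle(0.060, 0.005)
#' @export
ernstAngle <- function(T1, TR) {
  if (any(T1 <= 0) || any(TR <= 0)) stop("T1 and TR must be positive")
  acos(exp(-TR / T1)) * 180 / pi
}

#' Scan time of the radial protocol
#'
#' `nSpokes * TR * nAverages` seconds. [formatScanTime()] renders it as
#' "m:ss" (seconds floored) or as whole minutes (nearest): the single-average
#' radial protocol (15,460 spokes, TR 5 ms) takes 77.3 s = "1:17", and the
#' 12-average acquisition about 15 minutes.
#'
#' @param nSpokes number of spokes.
#' @param TR repetition time (s).
#' @param nAverages number of averages.
#' @return Scan time in seconds.
#' @examples
#' formatScanTime(scanTime(15460, 0.005, 1))        # "1:17"
#' formatScanTime(scanTime(15460, 0.005, 12), "minutes")
#' @export
scanTime <- function(nSpokes, TR, nAverages = 1) {
  if (any(nSpokes <= 0) || any(TR <= 0) || any(nAverages <= 0))
    stop("all scan-time inputs must be positive")
  nSpokes * TR * nAverages
}

#' @rdname scanTime
#' @param seconds scan time in seconds.
#' @param style `"mmss"` for "m:ss" (seconds floored) or `"minutes"` for the
#'   nearest whole number of minutes.
#' @export
formatScanTime <- function(seconds, style = c("mmss", "minutes")) {
  style <- match.arg(style)
  if (style == "mmss") {
    s <- floor(seconds)
    sprintf("%d:%02d", s %/% 60, s %% 60)
  } else {
    sprintf("%d min", round(seconds / 60))
  }
}
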