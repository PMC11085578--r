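---
title: "Simulating a quantitative sodium-MRI QA experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a quantitative sodium-MRI QA experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodiumQA)
```

## What this package models

Quantitative sodium (^23^Na) MRI estimates tissue sodium concentration (TSC)
from calibrated ^23^Na images. Because the sodium signal is three orders of
magnitude weaker than the proton signal (gyromagnetic ratio 11.26 MHz/T vs
42.57 MHz/T, low in-vivo concentration), quality-assurance protocols built
around dedicated phantoms are essential before any longitudinal or
multi-center claim can be trusted. sodiumQA re-creates such a QA experiment
entirely in software so that every stage — phantom, acquisition,
reconstruction, quantification, repeatability statistics — is deterministic,
testable and fast enough for continuous integration.

The simulated experiment follows a 3 T phantom protocol:

* a **dilution phantom**: 12 cylindrical saline vials in three sizes (50, 15
  and 7 mL) at 9.625, 19.25, 38.5 and 77 mM (a two-fold dilution series of
  physiological saline), arranged every 30° on a 5 cm ring with the size
  classes interleaved, plus a central 7 mL vial of undiluted 154 mM saline;
* a **3D radial golden-angle acquisition**: FOV 38.4 cm, nominal resolution
  1.86 mm, 15,460 center-out spokes, TR 5 ms, TE 0.5 ms (UTE), flip angle
  30°, readout 5 ms, 12 averages (total ≈ 15 min; 1:17 min per average);
* **gridding reconstruction** (density-compensated adjoint NUFFT) at 1.5 mm;
* **ROI quantification**: 13 circular ROIs on the central axial slice (12 mm
  for large vials, 8 mm otherwise), four 22.5 mm background noise ROIs, a
  noise-anchored linear regression of intensity against concentration fitted
  on the four large vials plus the background mean as a 0 mM point;
* **repeatability**: coefficient of variation (CoV, %) of the per-vial
  estimated concentrations, intra-day (3 scans of one session, n = 3) and
  inter-day (first scan of each of 3 sessions, n = 3).

## The forward model

Each non-background voxel of the rasterized phantom contributes

$$S(\mathbf{k}_j, t_j) \;=\; \sum_v C_v\,\Delta V\;
  \underbrace{\frac{\sin\alpha\,(1 - E_1)}{1 - E_1\cos\alpha}}_{\text{FLASH steady state}}\;
  d_v(t_j)\; e^{-2\pi i\,\mathbf{k}_j\cdot\mathbf{x}_v},
  \qquad E_1 = e^{-TR/T_1},$$

with bi-exponential transverse decay
$d_v(t) = f\,e^{-t/T_{2f}} + (1-f)\,e^{-t/T_{2s}}$. The Fourier sum is
evaluated **exactly** (compiled non-uniform DFT, no gridding approximation on
the forward side); decay is applied piecewise-constant over 8 readout time
segments by default, which keeps the sum factorable per segment. The test
suite compares the forward model against an independent plain-R brute-force
DFT at machine precision, per segment.

Defaults that matter:

* **Relaxation** — the physical phantom holds aqueous saline, so the default
  compartment is mono-exponential (`fastFraction = 0`, T2 = 50 ms,
  T1 = 60 ms). A bi-exponential `"agarose"` preset (3/25 ms, fast fraction
  0.6) is provided for tissue-mimicking scenarios.
* **Golden-angle scheme** — the 3D generalization via the two 2D golden
  means (`cos θ_m = 1 − 2 frac(m·0.46557…)`, `φ_m = 2π frac(m·0.68233…)`),
  the standard phyllotaxis construction for 3D radial MRI. Spoke directions
  cover the sphere near-uniformly for any spoke count.
* **Idealizations** — hard-pulse excitation with a perfectly uniform flip
  angle, uniform (birdcage-like) coil reception, no B0 inhomogeneity,
  off-resonance, gradient ramps or eddy currents. k-space is sampled
  uniformly along each spoke.
* **Noise** — i.i.d. complex Gaussian per sample and repeat, with
  per-repeat streams derived deterministically from the session seed.

## Reconstruction

`gridReconstruct()` implements the density-compensated adjoint NUFFT:
samples are weighted by analytic 3D radial density compensation (∝ k², with
the k = 0 sample assigned the central Nyquist cell volume, normalized to the
sampled k-space ball), spread onto a 2× oversampled Cartesian grid with a
width-4 Kaiser–Bessel kernel (shape parameter from the standard
minimum-aliasing prescription), inverse-FFT'd, deapodized by the kernel's
analytic transform and cropped. The same operation with `method = "dft"`
evaluates the adjoint sum exactly; the gridding path agrees with it to a
normalized RMS difference below 10⁻³ on test instances, and the
forward/adjoint pair passes an inner-product identity at 10⁻⁶. Magnitude
images feed quantification, matching scanner-side ROI practice (no Rician
bias correction — the background "0 mM" anchor is deliberately the biased
magnitude mean, as it would be on a console).

Alignment between sessions is translation-only at integer voxels, by the
peak of the FFT cross-correlation of magnitudes, with a peak-ratio
low-confidence flag for degenerate (noise-only) inputs. Simulated sessions
are aligned by construction; the operator exists to absorb injected
inter-day shifts.

## Quantification and its quirks

ROI placement is automatic from the vial registry (the physical experiment
draws ROIs manually on a proton reference; automation removes operator
variance while preserving the geometry). ROI centers snap to the nearest
voxel center, which is always included — on coarse desk-scale grids an 8 mm
ROI can be a single voxel. Background noise ROIs are replicated over an
axial depth equal to their diameter (a short cylinder) so that the pooled
background sample stays large enough for a stable SD on coarse grids; this
is a deliberate, documented departure from strictly planar noise ROIs.

The calibration regresses ROI mean intensity on known concentration using
the four **large** vials plus the pooled background mean at 0 mM; the
medium/small vials and the central 154 mM vial are test points (154 mM is an
extrapolation). Ordinary unweighted least squares is used. Because each
session refits its own line, estimates are invariant to any global intensity
scaling of the image — which is also why the injected per-day intensity
drift (below) does not inflate the inter-day CoV: it models a scanner-gain
effect the calibration is designed to remove.

## What the synthetic experiment reproduces — and what it does not

With noise calibrated so that the large 77 mM vial SNR ≈ 79 (the protocol's
flip-angle-30 regime), the simulated 3 scans/day × 3 day design reproduces
the headline QA claims:

* intra- and inter-day CoV below 20% for every vial at 38.5 and 77 mM
  (typically 1–7% in the simulation; acceptance runs report the maximum);
* CoV generally decreasing with concentration and vial size, with the
  smallest vials at 9.625–19.25 mM becoming unreliable (CoV tens of
  percent, rendered as ">50.0" where applicable);
* small vials underestimating concentration at matched nominal
  concentration — partial volume plus resolution/SNR limits;
* SNR(FA 30°) > SNR(FA 15°), and a flip-angle sweep over 10–50° peaking at
  20–30°, bracketing the analytic Ernst angle
  `acos(exp(−TR/T1)) = 23.1°` for T1 = 60 ms, TR = 5 ms (the closed form is
  returned as-is, not rounded to a nominal console angle);
* averaging 12 repeats buying ≈ √12 in SNR.

Known differences from real data. The noise floor of the reconstruction
contains structured point-spread sidelobes and angular-undersampling streaks
(accounted for explicitly by the noise calibration, which models the
background SD as an artifact floor plus thermal noise in quadrature). At
desk scale the medium vials slightly **over**estimate, because the coarse
PSF's Gibbs overshoot falls inside the 8 mm ROI — the monotone
small ≤ medium ≤ large ordering is therefore only asserted as small below
both larger sizes. B0 inhomogeneity, susceptibility from the air around the
vials, coil-profile shading, physiological drift and operator variance are
not modelled, so passing tests validate the *software pipeline and its
statistics*, not scanner hardware.

## Desk scaling and problem sizes

`scale` shrinks grids, spoke count and kmax together while preserving the
FOV, keeping the acquisition Nyquist-matched: `scale = 0.25` means a 64³
reconstruction at 6 mm, ≈ 3,865 spokes × 52 samples and a ≈ 1,880-voxel
phantom — a full 9-session repeatability experiment plus noise calibration
in about a minute on one CPU. The test suite runs its oracle comparisons on
≤ 16³ instances and the end-to-end checks at `scale = 0.25`/`0.125`; the
full-scale protocol is one `scale = 1` away and changes no code paths.

Numerical choices worth knowing: voxel-center rasterization (a voxel belongs
to a vial iff its center is inside the cylinder), even-sized grids with the
origin on a voxel center (`index = n/2 + 1`), spoke-major sample ordering,
analytic (not iterative) density compensation chosen for determinism, and a
fixed-point noise calibration that refuses targets above the
artifact-limited SNR ceiling.

## Coil bench arithmetic

The `bench`-side functions are closed forms: perturbing-sphere sensitivity

$$\eta = c_{\mathrm{pol}}
  \sqrt{\frac{\mu_0\,(f_1^2 - f_0^2)}{\pi^2\,B_w\,r_s^3\,f_0^2}},$$

with `c_pol = 1/2` (linear) or `1/√2` (quadrature — the drive power splits
over two channels), and the measured −3 dB bandwidth doubled when the coil
ports were open during the bench measurement (an explicit flag, since
closed-port measurements are equally valid inputs). The exact grouping of
the `π²` and bandwidth factors under the root follows from dimensional
analysis (η² must carry T²·s/J); the implementation enforces `f1 ≥ f0`
(a metallic sphere raises the resonance). Quality factor `Q = f0/Bw`,
Larmor frequency `γB0`, Ernst angle `acos(exp(−TR/T1))` and scan time
`nSpokes × TR × nAverages` round out the protocol arithmetic.

## A minimal session

```{r, eval = FALSE}
cfg <- runConfig(scale = 0.25)
phantom <- buildPhantom(cfg$phantom)

sigma <- calibrateNoiseSigma(phantom, cfg$acq, targetSnr = 79,
                             reconParams = cfg$recon, seed = 101L)

sessions <- runRepeatabilityExperiment(cfg, days = 3, scansPerDay = 3,
                                       baseSeed = 1L, sigma = as.numeric(sigma))
report <- repeatabilityReport(sessions)
formatReport(report)
```

The same pipeline is scriptable from a shell via
`inst/scripts/sodiumqa.R` (`simulate`, `reconstruct`, `quantify`, `report`,
`fa-calibrate`, `bench`), with YAML/JSON configs, an RDS k-space container
with a versioned schema, NIfTI-1 images and CSV/JSON tables; every artifact
records the configuration hash and seed for exact replay.
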