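---
title: "Modeling water-metabolite magnetization exchange in downfield 1H MRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling water-metabolite magnetization exchange in downfield 1H MRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfmx)
```

## The problem

Protons that resonate downfield of water (> 4.7 ppm) in the ¹H spectrum of
the human brain — the tryptophan indole NH at 10.1 ppm and the NAD⁺
nicotinamide H2, H6, and H4 protons at 9.3, 9.1, and 8.9 ppm — exchange
longitudinal magnetization with the water pool, either by chemical exchange
of the labile NH proton or by dipole–dipole cross-relaxation of the
non-labile nicotinamide protons. Under water-suppressed conditions this
exchange inflates the apparent T₁ of the metabolite; conversely, the
*difference* between recovery measured with water intact and recovery
measured with water saturated carries the exchange rate itself.

`dfmx` implements the full analysis chain for the paired saturation-recovery
experiment at 7 T: spectrally selective excitation (9.7 ± 1 ppm), a
*selective* saturation experiment that nulls only the metabolite band
(TS = 25, 50, 300, 600 ms), a *broadband* experiment that nulls metabolites
and water together (TS = 500, 1000, 2000, 4000 ms), and a no-saturation scan
treated as TS = 10 s. Because no raw in-vivo spectra are publicly deposited,
the package pairs the analysis chain with a fully parameterized simulator so
that every stage is testable against known ground truth.

## Models

**Model 1 (apparent T₁).** Each experiment's amplitude-vs-TS series is fit
with the three-parameter saturation-recovery curve

$$S(TS) = M_0\,\bigl(1 - k\,e^{-TS/T_1}\bigr),$$

where $k \in [0, 1]$ is the saturation efficiency and $T_1$ is *apparent*:
it folds exchange into an effective recovery rate. Fitting is bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`) with $k \in [0,1]$ and $T_1 > 0$.
A constant series returns $k = 0$ with $T_1$ undefined; a fit pinned at the
T₁ box carries no recovery information and is flagged invalid.

**Model 2 (two-pool Solomon system).** Longitudinal magnetization of the
metabolite (spin A) and water (spin B) pools obeys

$$\frac{dM_{z,A}}{dt} = -\frac{M_{z,A}-M_{0,A}}{T_{1,A}}
  - \sigma_{AB}(M_{z,A}-M_{0,A}) + \sigma_{BA}(M_{z,B}-M_{0,B}),$$

with the symmetric equation for spin B and the equilibrium constraint
$\sigma_{BA} = \sigma_{AB}\,M_{0,A}/M_{0,B}$. Fixed assumptions follow the
in-vivo protocol: water T₁ = 1800 ms and
$M_{0,B}/M_{0,A} = (2 \times 55\ \mathrm{M}) / (0.3\ \mathrm{mM})$ (two water
protons at 55 M against 0.3 mM metabolite). Initial conditions distinguish
the experiments: selective saturation starts at
$(M_{0,A}(1-k_{sel}),\, M_{0,B})$, broadband at
$(M_{0,A}(1-k_{broad}),\, M_{0,B}(1-k_{broad}))$, with both efficiencies
*fixed* at their Model 1 estimates. The free parameters are the
exchange-corrected $T_{1,A}$, the exchange rate $\sigma_{AB}$, and a nuisance
amplitude $M_{0,A}$ (amplitude units are arbitrary after regression), fit by
minimizing the summed squared residuals of both experiments jointly.

Because the deviation variables follow a linear 2×2 system, the solution is
a bi-exponential available in closed form from the eigen-decomposition;
`two_spin_solve()` also offers a `deSolve`-based numeric route
(`rtol = 1e-11`) used purely as an independent cross-check — the package's
test suite verifies agreement to better than 1e-8 of $M_{0,A}$ over 1000
random parameter draws. The near-defective case (eigenvalue gap below
1e-10 of the trace) switches to the first-order expansion of the matrix
exponential, and eigenvectors are taken from whichever nullspace formula has
the larger norm, which keeps the basis well-conditioned when the system
decouples ($\sigma_{AB} = 0$).

**Why the contrast works.** With selective saturation, water stays at
equilibrium and the metabolite recovers at rate $1/T_{1,A} + \sigma_{AB}$.
With broadband saturation, the recovering water pool continuously feeds the
metabolite through $\sigma_{BA}(M_{z,B}-M_{0,B})$ — a term of order
$\sigma_{AB} k M_{0,A}$ despite the tiny $\sigma_{BA}$, because the water
deviation is enormous on the metabolite scale — so the apparent recovery is
dragged toward the water T₁. The broadband/selective apparent-T₁ ratio is 1
without exchange and grows monotonically with $\sigma_{AB}$ (a property the
acceptance suite checks).

## Optimization

The joint Model 2 objective has a curved ridge: when exchange dominates
($\sigma_{AB} \gg 1/T_{1,A}$), wide ranges of $T_{1,A}$ fit almost equally
well. Two measures address this:

* the local solver (`nlminb`) runs in $(\log T_{1,A},\ \sigma_{AB},\ \log
  M_{0,A})$ coordinates so all parameters move on comparable scales, and
* the local solves are wrapped in seeded basin hopping (default 10 hops):
  random perturbations of the current minimum (log-normal on $T_{1,A}$ and
  $M_{0,A}$, reflected normal on $\sigma_{AB}$), each followed by a bounded
  local fit and a Metropolis accept/reject; the best minimum found is
  returned, deterministically for a given seed.

Bounds are $T_{1,A} \in [50, 10^4]$ ms and $\sigma_{AB} \in [0, 100]$ Hz. A
fit that converges onto the $T_{1,A}$ box is *flagged* (`at_boundary`) but
retained: the likelihood there is nearly flat in $T_{1,A}$, the box edge is
effectively the profile boundary, and the exchange rate remains well
determined. Discarding such fits would produce far more missing cells than
the in-vivo analysis reports.

## The simulator

`generate_saturation_series()` produces, per subject, the two saturation
experiments, the no-saturation scan, and a water reference scan, as
multi-channel complex FIDs:

* **Lines.** Each resonance is a damped complex exponential with damping
  $\pi \times$ FWHM; default linewidths are the in-vivo values (TRP 54 Hz,
  H2 28, H6 32, H4 38). H6 and H4 are doublets (J = 6 and 8 Hz, standard
  nicotinamide couplings, unresolved at these linewidths), synthesized as
  two half-amplitude lines.
* **Excitation window.** The spectrally selective pulse is modeled as a
  fourth-order super-Gaussian, $\exp(-\ln 2\,(2\Delta/\mathrm{FWHM})^4)$:
  exactly 1 at 9.7 ppm, exactly 0.5 at ± 1 ppm, smooth and monotone per
  side. (An apodized-sinc magnitude lobe was considered; the super-Gaussian
  satisfies the same constraints — half maximum at the stated width,
  transition-band attenuation ≈ 0.75 at the H4 position — without numerical
  root-finding for the half-max scale.)
* **Baseline.** The adenosine/NAA/amide complex directly upfield of NAD⁺ is
  emulated as three broad Lorentzians at 8.2–8.7 ppm, attenuated by the
  excitation window, recovering mono-exponentially (T₁ 300 ms). It exists to
  exercise baseline handling realistically — its overlap with the H4 window
  is the main driver of H4 fit fragility, matching the in-vivo experience.
* **Amplitude dynamics.** At every TS each target resonance's amplitude is
  the closed-form two-pool solution under that subject's ground-truth
  parameters; the no-saturation scan is generated at exact equilibrium. (The
  analysis assigns it TS = 10 s, where the broadband solution is ~0.3% below
  equilibrium — a small systematic the in-vivo protocol shares.)
* **Channels and noise.** Each of 8 channels applies a complex sensitivity
  (magnitude 0.7–1.3, random phase, encoded in the water reference) and adds
  stationary complex Gaussian noise, independent across channels, no
  per-transient frequency or phase jitter. `noise_sigma = 0.44` was
  calibrated by simulation (two scale-and-remeasure passes) so the measured
  NAD⁺ H2 spectral SNR of the processed no-saturation scan is ≈ 27.4.
* **Problem sizes.** 3 kHz sweep, 1024 complex points, carrier at the
  9.7 ppm excitation center — enough to cover 7.5–12 ppm with 2.9 Hz bins.
  Eight channels rather than 32 keeps the simulator light; the difference is
  only the matched-filter gain, which the calibration absorbs.

The default cohort sampler draws subject truths at the published cohort
means/SDs (corrected T₁ and exchange rates for the four resonances),
truncated to physical ranges; saturation efficiencies default to 0.85
(0.6 for selective saturation of H4, which sits on the pulse transition
band) with small jitter. These two efficiency values are placeholders — the
in-vivo report states only that all efficiencies exceeded 0.7 except
selective H4.

What the simulator does *not* emulate: B₀/B₁ inhomogeneity, per-transient
motion and phase drift, eddy currents, chemically realistic macromolecule
baselines, or NEX-dependent noise differences between scan types (one noise
level is used for all scans). Passing tests therefore demonstrate
correctness of the estimation chain under idealized-but-calibrated
conditions, not robustness to every in-vivo artifact.

## Processing and peak fitting

* **Channel alignment and rejection.** Channel-wise frequency corrections
  (integer spectral bins, up to ± 20 Hz) maximize the correlation of each
  channel's lightly smoothed (9-bin boxcar) magnitude spectrum with the
  channel average over 8.5–10.5 ppm; channels whose best correlation stays
  below 0.7 are rejected. Corrections are estimated once per subject on the
  no-saturation scan — channel frequency offsets are session properties, and
  the most-saturated scans do not contain enough signal to estimate them —
  then applied to all scans. The similarity metric and threshold are
  stand-ins: the in-vivo pipeline cites an external method without formulas.
* **Coil combination.** Matched filter: weights are conjugates of the
  water-reference channel amplitudes (spectral-peak estimate by default;
  first-point estimate behind a flag), normalized to unit total power.
* **Apodization.** 5 Hz exponential line broadening.
* **HSVD.** The no-saturation scan is decomposed into damped complex
  exponentials: Hankel matrix with `floor(N/2)` rows, SVD truncated at 60
  components *and* at the numerical rank (singular values above 1e-10 of the
  largest — below that the singular vectors carry no signal and emit
  spurious pole pairs with large mutually-cancelling amplitudes), poles from
  the shift-invariance eigenproblem, growing components discarded,
  amplitudes by linear least squares.
* **Assignment.** One component per resonance — the largest-magnitude
  component within ± 0.08 ppm of the nominal shift (also for the doublets,
  which HSVD does not resolve at these linewidths); an empty window marks
  the resonance missing rather than failing. All other components are
  baseline.
* **Fixed-basis regression.** Every scan is regressed (complex linear least
  squares in the time domain) onto the assigned components with frequencies
  and dampings frozen; baseline components falling in 7.9–8.85 ppm ride
  along as per-scan nuisance regressors. Unassigned components *outside*
  that band are excluded from the design: they are mostly noise fragments
  (often split off the broad TRP line) and, left in, they siphon
  scan-dependent signal from the targets. R² is reported over the fitted
  7.9–10.6 ppm band in the frequency domain (the unitary transform makes
  this a band-restricted residual ratio); full-bandwidth R² would be diluted
  by out-of-band noise into a basis-independent constant.
* **Amplitude scalar and QC.** Scan amplitudes are phased by the equilibrium
  scan (real part along the equilibrium phase), making the TS = 10 s point
  positive real. A resonance whose equilibrium amplitude falls below 5 times
  its regression standard error — the SE comes from the complex-LS Gram
  inverse and so accounts for baseline collinearity — is dropped for that
  subject, the package's formalization of the in-vivo rule of omitting
  poorly fitted peaks.

## Statistics

Cohort cells are summarized as arithmetic mean ± sample SD (n−1 denominator;
this convention reproduces the published summary row exactly), with explicit
missing values. Selective vs broadband apparent T₁ uses a paired t-test by
default (same subjects under both conditions; the unpaired form is a flag),
with the zero-variance degenerate case returning t = 0, p = 1. Ratios,
corrected T₁, and exchange rates are compared across resonances by one-way
ANOVA followed by Tukey HSD.

## Accuracy at the study conditions

On noiseless input the chain is exact: HSVD poles to ~1e-12, basis-generated
regression to 1e-10, Model 1 and Model 2 recovery to machine precision, and
closed-form vs numeric solver agreement below 1e-8. At the calibrated SNR,
the per-point amplitude noise of the full pipeline sits at its least-squares
floor — about 4% of equilibrium for the H2 and TRP singlets, ~7% for H6 and
~16% for H4, the latter two inflated by the unresolved doublet convention
and baseline overlap. Exchange-rate errors scale accordingly: the ordering
σ(TRP) > σ(NAD⁺) is recovered essentially always at n = 8, while per-subject
σ estimates carry median relative errors of roughly 15% (H2) to 50% (H4),
and the corrected T₁ is only weakly identified when exchange dominates the
selective recovery rate — consistent with the very large between-subject
spread of the published corrected-T₁ values. The replicate ordering study
runs at the amplitude-series level with per-resonance noise SDs measured
from full-pipeline simulations (`measure_amplitude_noise()`), which
preserves the quantity under test at a fraction of the cost of re-running
HSVD thousands of times; basin hopping uses 3 hops there (the data-driven
start converges in nearly all fits) and 10 elsewhere.

## Known limitations

* Two pools only; multi-pool exchange, fitted water T₁, and B₁-corrected
  saturation modeling are out of scope.
* The metabolite:water equilibrium ratio uses the NAD⁺ brain concentration
  for all resonances, tryptophan included — kept for fidelity to the in-vivo
  analysis; it rescales σ_BA only and has negligible effect on the fitted
  quantities.
* Saturation efficiencies are fixed at Model 1 estimates, so Model 1 noise
  propagates into Model 2 — inherent to the two-stage design.
* The TS = 10 s equilibrium assignment is ~0.3% optimistic for the broadband
  experiment (see above).
* The amplitude-vs-TS series treats points as homoscedastic; a weighted
  variant could use the regression SEs but the gain is small when all scans
  share one noise level.
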