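---
title: "Methods: simulating and analysing deuterium metabolic imaging repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing deuterium metabolic imaging repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`dmirep` implements a complete test–retest analysis chain for deuterium
metabolic imaging (DMI) of the brain at clinical field strength, together
with a synthetic-study generator that makes every stage testable without
any scanner data. DMI measures the uptake of orally administered
deuterated glucose and its conversion to glutamate+glutamine (Glx) and
lactate through chemical-shift imaging (CSI) of the deuterium resonance:
each voxel of a coarse spatial grid carries a full free-induction decay
(FID) whose spectrum shows four resolvable ²H lines — water, glucose, Glx
and lactate.

The package covers: CSI simulation with subject- and session-level variance
components; spectral reconstruction (FFT with zero filling, no
apodization); Marchenko–Pastur PCA denoising with automatic rank
selection; prior-knowledge time-domain Lorentzian fitting with Cramér–Rao
lower bounds (CRLB) and voxel quality control; saturation, Richardson–Lucy
partial-volume and polynomial bias-field corrections; three quantification
modes (baseline water, external phantoms, internal cerebellum reference);
and the repeatability statistics — within-subject coefficient of variation
(CoV), repeatability coefficient, between-subject CoV, Bland–Altman limits
of agreement and quadratic dynamics fits.

# Signal model

Every voxel's FID is a sum of damped complex exponentials,

$$ y(t) \;=\; e^{i\varphi} \sum_{k=1}^{4} a_k \,
   e^{(2\pi i f_k - d_k)\,t}, $$

with amplitude $a_k \ge 0$ (proportional to concentration), frequency
offset $f_k$ from water, damping $d_k$ (Lorentzian FWHM $= d_k/\pi$), and
one zero-order phase $\varphi$ shared by all resonances; relative phases
are fixed at zero and no first-order phase is modelled. Chemical shifts
default to water 4.8, glucose 3.8, Glx 2.4 and lactate 1.3 ppm at a ²H
Larmor frequency of 19.6 MHz (1 ppm ≈ 19.6 Hz); all of these live in the
`resonance_priors()` table and are configuration, not constants. The
glucose multiplet is modelled as a single Lorentzian, which is adequate at
the ~7 Hz spectral resolution of a 700-point, 5000-Hz acquisition.

The fit (`fit_voxel()`, `fit_grid()`) is bounded nonlinear least squares on
the stacked real/imaginary residuals: Levenberg–Marquardt with an analytic
Jacobian, Nielsen's gain-ratio damping update, box constraints by
projection with an active-set freeze for parameters pinned at a bound, and
a windowed plateau stop (20-iteration window, relative progress below
1e-6) besides the primary relative-cost tolerance of 1e-10 and a 500
iteration cap. Frequencies are constrained to ±0.3 ppm around the prior
centers and linewidths to 1–50 Hz FWHM. Starting amplitudes come from a
complex linear least-squares projection of the FID onto the prior basis.
A voxel that stalls or is identically zero is flagged, never an error.

CRLB percentages are computed from the inverse Fisher information of the
time-domain model at the fitted parameters,
$100\,\sigma\sqrt{[(J^\top J)^{-1}]_{kk}}/a_k$, using either a supplied
noise level or the per-voxel estimate from the last 10% of the FID.

## Linewidth convention

Linewidths are *measured* on magnitude spectra (no phasing step is
needed), but a Lorentzian's magnitude profile is $\sqrt{3}$ wider than its
absorption profile. `spectrum_metrics()` therefore divides the measured
half-maximum width by $\sqrt 3$ and reports the conventional absorption
FWHM, directly comparable to $d/\pi$ and to the 30-Hz quality gate.

# The synthetic study generator

`simulate_study()` (and the streaming equivalent inside `run_pipeline()`)
emulates a two-session, four-timepoint (0, 30, 75, 120 min) study of six
subjects on a 10×10×10 grid over a 240-mm field of view, 700 spectral
points at 5000 Hz, 70° flip angle and 155.8 ms repetition time.

**Atlas.** `make_atlas()` builds a deliberately parametric head: an
ellipsoidal brain carved into four lobes by anterior/posterior position
and height, spherical cerebellum, thalamus, caudate, putamen and brain
stem, and two external phantom spheres. On very coarse grids a region
whose shape captures no voxel center claims its nearest eligible voxel, so
every region is always non-empty. No registration stage exists because
simulation and analysis share one space.

**Dynamics.** Population concentration curves are quadratic in time,
$c(t) = \beta_1 t + \beta_2 t^2$ (mM, minutes). Defaults give glucose and
lactate a plateau between 75 and 120 min with peaks near 3.0 and 1.55 mM,
and water and Glx near-linear growth reaching ≈3.9 mM above baseline and
≈3.2 mM at 120 min — the published whole-brain trajectory shapes and peak
levels. Water additionally carries the natural-abundance HDO baseline,
default 10.12 mM (configuration; the literature-standard value for
baseline-referenced quantification).

**Variance components.** A per-subject and a per-session mean-one
log-normal effect multiply each metabolite's curve, parameterised by their
CoV ($\sigma_{\log} = \sqrt{\ln(1+\mathrm{CoV}^2)}$; log-normality
guarantees positivity). Defaults are 18% between subjects and 9% between
sessions — the magnitude of the published 120-min whole-brain estimates.
Effects are drawn independently per metabolite. Regional multipliers
(defaults spanning ~20% for water and glucose, ~40% for Glx, ~60% for
lactate) reproduce the observed regional heterogeneity. At baseline the
labelled species are exactly zero and water is exactly the natural
abundance level.

**B1 field.** Transmit–receive inhomogeneity is a smooth radial quadratic,
$1+\beta(1-2r^2)$, scaled so the span from center to corner is $\pm\beta$.
Each session draws $\beta \sim U(0, 0.07)$, matching the ±7% span measured
for this coil class. The draw is per session, not global: a field
identical in every exam would cancel out of every normalization mode and
could not contribute to between-subject variance at all; session-to-session
amplitude variation is how coil loading and positioning differences enter.

**Noise.** I.i.d. complex Gaussian noise with per-channel standard
deviation 2.7 (in units where 1 mM of fully relaxed signal has amplitude
1). This value comes from a closed-form calibration: with the steady-state
saturation factor of water (0.459 at 70°/155.8 ms/T1 320 ms) and a 10-Hz
linewidth, it puts the whole-brain water spectral SNR at ≈14 at 120 min
and ≈10 at baseline — the published quality-control levels. Metabolite
SNRs then land at the published order of magnitude (glucose ≈6, Glx ≈3,
lactate ≈1–3) without further tuning.

**What the generator does not emulate.** No k-space trajectory, gradient
or physical sequence modelling; no spatial point-spread blur (each voxel's
FID is generated from its own concentration); crisp rather than
probabilistic labels; no motion, lipid contamination, baseline roll or
frequency drift. Passing tests therefore demonstrate the correctness of
the analysis chain and its statistical calibration — not robustness to
every artifact of real scanner data.

# Processing pipelines

Two variants mirror common practice:

* **simple** — reconstruct, fit, saturation-correct, quantify;
* **extended** — Marchenko–Pastur PCA denoising before the fit, then
  Richardson–Lucy partial-volume correction and bias-field correction of
  the amplitude maps (in that order), then saturation correction and
  quantification.

**Quality control.** Voxels are retained only if the *pre-processing*
(raw-spectrum) water SNR exceeds 5 and the water linewidth is at most
30 Hz. The SNR estimator is spectral — peak magnitude over the standard
deviation of the real part in the outer 10% of the spectral edges
(metabolite-free by construction). A time-domain variant (fitted
amplitude over FID-tail noise) exists as configuration, but the spectral
form is the default because it reproduces the published Table-1 scale
(water ≈10 at baseline), on which a gate at 5 excludes almost nothing —
matching the published exclusion count of ~0.2 voxels per exam. The
time-domain estimator reads ≈1.7 on identical data and would discard every
voxel at that threshold.

**Denoising.** Sliding 3×3×3 patches (stride 1), Casorati matrices with
rows = patch voxels and columns = spectral points, complex
eigendecomposition of the spatial Gram matrix, truncation at the
Marchenko–Pastur rank, uniform averaging of overlapping estimates. The
rank rule retains the smallest leading set such that the spread of the
discarded eigenvalues fits within the MP bulk width implied by their own
mean ($\lambda_{p+1}-\lambda_m \le 4\sqrt{(m-p)/n}\,\bar\lambda_{\rm
tail}$). Denoising runs per exam; joint denoising across timepoints was
evaluated and brought no measurable benefit on whole-brain summaries, so
the simpler per-exam default stands.

**Baseline exams.** The baseline scan contains only natural-abundance
water and serves purely as the quantification reference, so only the water
resonance is fitted there.

**Partial-volume correction.** Standard multiplicative Richardson–Lucy
iterations (default 10) with a configurable kernel: a Gaussian surrogate
(σ = 0.6 voxel) by default, or `psf_csi()`, the cell-integrated Dirichlet
response of the Fourier encoding. Because the simulator applies no spatial
blur, this stage is validated on constructed forward-blur oracles and kept
in the pipeline for structural parity; it conserves flux exactly.

**Bias-field correction.** A second-order polynomial is fitted to the log
intensities of the (well-conditioned, strictly positive) water map inside
the QC mask, and the resulting multiplicative field is divided out of all
metabolite maps of that exam, preserving each map's mask mean exactly.
Estimating one shared field from water avoids fitting polynomials to
near-zero metabolite maps (log-intensities are undefined at baseline
levels) and reflects that the underlying B1 bias is common to all
resonances.

**Quantification.** Three modes:
baseline (voxel-wise ratio to the same session's baseline water map times
10.12 mM — absolute concentrations, requires the extra scan), phantom
(two-point line through the 6.4 and 19.15 mM external references —
absolute, single exam), and cerebellum (ratio to the same exam's
cerebellum mean — unitless, single exam). Cerebellum normalization divides
the voxel maps by the scalar cerebellum mean; dividing regional means by
the cerebellum mean gives identical regional results, so the two readings
of "normalize to the cerebellum" coincide here. Re-quantifying an already
quantified map is rejected via the units tag, and every operation appends
to the map's provenance chain.

# Statistics

For matched exams the package computes, per metabolite × timepoint ×
region:

$$ \mathrm{bsCoV} = 100\,\frac{\mathrm{SD}(\bar v_i)}{\overline{v}},
\qquad
\mathrm{wsCoV} = 100\,
  \frac{\mathrm{SD}(v_{i2}-v_{i1})/\sqrt2}{\overline{v}},
\qquad
\mathrm{RC} = 1.96\sqrt2\,\mathrm{wsCoV}, $$

with $n-1$ standard deviations throughout, sessions averaged per subject
before the between-subject CoV, and the grand mean of all observations as
the denominator (the formula's "relative measure" convention; a
per-subject-pair-mean variant is available and identical for complete
pairs). The RC/wsCoV ratio is the constant $1.96\sqrt2 = 2.7719$ on every
emitted row, which the tests assert. Bland–Altman bias and limits of
agreement and the pooled quadratic dynamics fit complete the statistical
surface.

# Calibration findings and limitations

The end-to-end calibration check simulates studies with configured 9%
within- and 18% between-subject CoV (6 subjects, 2 sessions, reduced
6×6×6 grid for runtime; about 100 replicate studies) and re-estimates both
through the full extended pipeline. Two opposing effects shape the
estimates: with only six subjects the CoV estimators' medians sit ~10%
below their expectations (few-degrees-of-freedom SD), while each exam's
measurement error inflates the session-to-session spread.

Measurement error at this grid size and the calibrated SNR is strongly
metabolite-dependent. The whole-brain glucose estimate carries ≈3–4%
per-exam error; glucose is therefore the calibration readout. Glx carries
≈7–8% — of the same order as the 9% session effect it would be probing —
with an information-theoretic floor around 5% (the CRLB of the
brain-averaged spectrum): a Glx-based recovery check is structurally
uninformative at this scale, and the vignette states this openly rather
than widening any tolerance. Lactate, whose single-voxel CRLB exceeds 50%
at these SNRs (as in the published quality tables), is likewise excluded
from calibration readouts. For the same reason the published Tables 1–4
values themselves — products of six real volunteers — are reproduced in
magnitude and ordering, not digit by digit.

Known limitations: Lorentzian-only lineshapes (no Voigt, no baseline
splines); no first-order phase; phase wrapping at ±π is not handled (all
simulated phases are far from the wrap); the phantom calibration line is
two-point, so its CoV under B1 variation is intentionally pessimistic;
and the regional tables use the acquisition grid (Fourier interpolation
to display resolution exists but analysis defaults to the native grid,
avoiding interpolation-correlated voxels in the statistics).

# Problem sizes used by tests and the acceptance script

Unit tests run single exams at 6×6×6×700. The calibration check uses 100
replicate studies (acceptance test) and 40 (acceptance script summary) at
6×6×6, two timepoints; the normalization comparison uses 12–20 replicate
studies in the simple variant; Monte-Carlo fitting checks use 200 noise
draws; one full-scale 10×10×10, four-timepoint, six-subject study is
processed end to end in the acceptance script. These sizes are the
package's choices for a desk-class reproduction of a study-scale analysis.
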