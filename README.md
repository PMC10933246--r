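# dmirep

Test–retest repeatability analysis for deuterium metabolic imaging (DMI)
of the brain at clinical field strength, with a synthetic-study generator
that makes the whole chain reproducible without scanner data.

DMI images the uptake of orally administered [6,6′-²H₂]glucose and its
conversion into glutamate+glutamine (Glx), lactate and water through
chemical-shift imaging of the deuterium resonance: a coarse (10×10×10)
spatial grid in which every voxel carries a 700-point free-induction decay
sampled at 5000 Hz. The central scientific question the package serves is
*how repeatable* such measurements are across scan sessions — the quantity
that decides whether scan–rescan DMI can detect treatment response in
individual patients.

The package is aimed at MR physicists and imaging statisticians designing
or simulating DMI studies: it provides every stage from raw FIDs to the
repeatability tables, plus a generative model to calibrate the statistics
against known ground truth.

## What it implements

* **Simulation** (`make_atlas`, `sample_truth`, `synthesize_csi`,
  `simulate_study`): a parametric head atlas (lobes, cerebellum, deep
  nuclei, brain stem, two external phantoms), quadratic-in-time population
  concentration curves with log-normal subject- and session-level random
  effects, per-session ±7 % B1 inhomogeneity, partial-saturation physics
  (70° flip, TR 155.8 ms) and calibrated complex Gaussian noise.
* **Spectral core** (`fid_model`, `reconstruct_spectrum`,
  `spectrum_metrics`): the damped complex-exponential signal model, FFT
  reconstruction with zero filling and no apodization, spectral SNR and
  linewidth metrics.
* **Denoising** (`mp_rank_select`, `denoise_grid`): sliding-patch PCA with
  automatic Marchenko–Pastur rank selection on complex Casorati matrices.
* **Fitting** (`fit_voxel`, `fit_grid`, `crlb_percent`, `qc_mask`):
  prior-knowledge bounded time-domain least squares for the four ²H
  resonances (compiled Levenberg–Marquardt with analytic Jacobian),
  Cramér–Rao lower bounds, and the voxel quality gates
  (water SNR > 5, linewidth ≤ 30 Hz).
* **Maps and quantification** (`saturation_correct`,
  `partial_volume_correct`, `bias_field_correct`, `fourier_interpolate`,
  `quantify`, `regional_means`): Richardson–Lucy deconvolution,
  polynomial bias-field removal, and three normalization modes — baseline
  water (mM), external phantoms (mM), internal cerebellum reference
  (ratio).
* **Statistics** (`between_subject_cov`, `within_subject_cov`,
  `repeatability_coefficient`, `bland_altman`, `dynamics_fit`,
  `repeatability_table`):

  within-subject CoV = 100 · (SD(Exam₂ − Exam₁)/√2) / mean,
  repeatability coefficient = 1.96·√2 · wsCoV,
  between-subject CoV = 100 · SD/mean (sessions averaged per subject),

  with n−1 standard deviations throughout.
* **Orchestration** (`pipeline_config`, `run_pipeline`): the *simple*
  (FFT + fit) and *extended* (denoise + fit + partial-volume + bias-field)
  processing variants, end to end from one seeded configuration to
  regional tables and repeatability tables, streaming one exam at a time.

## Worked example

Simulate a six-subject, two-session study on a reduced 6×6×6 grid with 18 %
between-subject and 9 % within-subject variability, process it with the
extended pipeline, and quantify against the baseline water signal:

```r
library(dmirep)

cfg <- pipeline_config(
  design  = study_design(n_subjects = 6, n_sessions = 2,
                         timepoints_min = c(0, 120), seed = 42),
  acq     = acq_params(matrix = c(6, 6, 6)),
  vp      = variance_params(between_subject_cov = 0.18,
                            within_subject_cov  = 0.09),
  variant = "extended", modes = "baseline")
res <- run_pipeline(cfg)
print(res)
```

```
DMI pipeline result (extended variant)
exams: 24  mean excluded voxels: 0

mode baseline (whole brain):
 metabolite timepoint within_subject_cov_pct repeatability_coefficient_pct
      water       120               3.359754                      9.312763
    glucose       120               9.837036                     27.266872
        glx       120              14.694485                     40.731034
    lactate       120              14.477839                     40.130522
 between_subject_cov_pct
                6.135284
               19.151346
               17.482259
               27.476196
```

Reading the glucose row: across the two sessions the whole-brain glucose
concentration of the same subject varies by ~9.8 % (so an individual
change larger than the repeatability coefficient, ~27 %, is unlikely to be
measurement noise), while subjects differ from each other by ~19 % — the
configured 9 %/18 % generative variance components recovered through the
complete measurement chain, inflated slightly by fit noise. Water appears
far more repeatable because its session effect only acts on the labelled
rise above the constant 10.12 mM natural-abundance background. The
`res$regional` table holds the per-exam regional means behind these
summaries, in mM for baseline mode.

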