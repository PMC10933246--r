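#' Test-retest study design
#'
#' @param n_subjects number of subjects.
#' @param n_sessions number of scan sessions per subject (>= 1).
#' @param timepoints_min imaging timepoints in minutes after tracer intake;
#'   must be sorted ascending and include 0 (the baseline scan).
#' @param seed integer seed from which all study randomness derives.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_subjects = 6L, n_sessions = 2L,
                         timepoints_min = c(0, 30, 75, 120), seed = 1L) {
  stopifnot(n_subjects >= 1L, n_sessions >= 1L,
            length(timepoints_min) >= 1L,
            !is.unsorted(timepoints_min, strictly = TRUE),
            timepoints_min[1] == 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 timepoints_min = timepoints_min,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Generative variance and signal parameters of the synthetic study
#'
#' Population concentration dynamics are quadratic in time,
#' `c(t) = lin * t + quad * t^2` (mM, t in minutes), describing the rise of
#' each deuterated species above its baseline; water additionally carries
#' the natural-abundance HDO baseline. Defaults give glucose and lactate a
#' plateau between 75 and 120 min (peaks ~3.0 and ~1.55 mM) and water and
#' Glx near-linear growth (Glx ~3.2 mM at 120 min). Subject- and
#' session-level random effects are mean-one log-normal with the given
#' coefficients of variation; regional multipliers scale the curves per
#' brain region. `noise_sd` is the standard deviation of the real and
#' imaginary parts of the additive complex noise per FID point, calibrated
#' so the whole-brain water spectral SNR is about 14 at 120 min.
#'
#' @param between_subject_cov,within_subject_cov fractional CoVs (>= 0) of
#'   the subject- and session-level log-normal effects.
#' @param noise_sd complex-noise standard deviation per FID point (>= 0).
#' @param b1_amplitude_range peak-to-center fractional span of the simulated
#'   B1 field; each session draws its own amplitude uniformly from
#'   `[0, b1_amplitude_range]`.
#' @param curves named list of `c(lin, quad)` coefficients per metabolite.
#' @param natural_abundance_mm baseline naturally abundant HDO (mM).
#' @param phantom_mm concentrations of the low and high external phantoms.
#' @param regional_multipliers named list (metabolite -> named region
#'   vector) of positive factors applied to the concentration curves.
#' @param lw_true_hz true Lorentzian linewidths (FWHM, Hz) per metabolite
#'   used by the simulator; defaults to the fitting priors' initial values.
#' @return object of class `variance_params`.
#' @export
variance_params <- function(between_subject_cov = 0.18,
                            within_subject_cov = 0.09,
                            noise_sd = 2.7,
                            b1_amplitude_range = 0.07,
                            curves = list(
                              water   = c(0.0280,  4.0e-05),
                              glucose = c(0.0615, -3.1e-04),
                              glx     = c(0.0220,  4.0e-05),
                              lactate = c(0.0316, -1.6e-04)),
                            natural_abundance_mm = 10.12,
                            phantom_mm = c(low = 6.4, high = 19.15),
                            regional_multipliers = default_regional_multipliers(),
                            lw_true_hz = NULL) {
  stopifnot(between_subject_cov >= 0, within_subject_cov >= 0,
            noise_sd >= 0, b1_amplitude_range >= 0,
            natural_abundance_mm > 0, length(phantom_mm) == 2L,
            all(phantom_mm > 0), phantom_mm[1] != phantom_mm[2])
  mult_ok <- vapply(regional_multipliers, function(m) all(m > 0), logical(1))
  if (!all(mult_ok)) stop("regional multipliers must be positive")
  structure(list(between_subject_cov = between_subject_cov,
                 within_subject_cov = within_subject_cov,
                 noise_sd = noise_sd,
                 b1_amplitude_range = b1_amplitude_range,
                 curves = curves,
                 natural_abundance_mm = natural_abundance_mm,
                 phantom_mm = phantom_mm,
                 regional_multipliers = regional_multipliers,
                 lw_true_hz = lw_true_hz),
            class = "variance_params")
}

#' Default regional concentration multipliers
#'
#' Emulates the observed regional heterogeneity: water and glucose vary by
#' about 20% across the brain, Glx by about 40% and lactate by about 60%.
#' @return named list metabolite -> named region factor vector.
#' @export
default_regional_multipliers <- function() {
  regions <- c("frontal", "parietal", "temporal", "occipital", "cerebellum",
               "thalamus", "caudate", "putamen", "brain_stem")
  mk <- function(v) stats::setNames(v, regions)
  list(
    water   = mk(c(1.05, 1.05, 0.95, 1.00, 1.00, 1.05, 0.95, 0.95, 0.90)),
    glucose = mk(c(1.05, 1.05, 0.95, 1.00, 1.10, 1.00, 0.95, 0.90, 0.90)),
    glx     = mk(c(1.10, 1.05, 0.95, 1.00, 1.20, 1.10, 0.90, 0.95, 0.80)),
    lactate = mk(c(1.15, 1.05, 0.90, 1.00, 1.30, 1.10, 0.85, 0.90, 0.70))
  )
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# mean-one log-normal deviates with coefficient of variation cov
rlnorm_cov <- function(n, cov) {
  if (cov <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cov^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Sample the ground-truth concentration table of a study
#'
#' Applies, in order: the population curve, a per-subject mean-one
#' log-normal effect (CoV `between_subject_cov`), a per-session mean-one
#' log-normal effect (CoV `within_subject_cov`), and the regional
#' multiplier. Both effects are drawn independently per metabolite. At the
#' baseline timepoint glucose, Glx and lactate are exactly zero and water
#' equals the natural-abundance level in every region. Reproducible from
#' `design$seed`.
#'
#' @param design a [study_design()].
#' @param atlas a `label_atlas` (defines the brain regions).
#' @param vp a [variance_params()].
#' @return data.frame with columns `subject`, `session`, `timepoint_min`,
#'   `region`, `metabolite`, `conc_mm`.
#' @export
sample_truth <- function(design, atlas, vp) {
  mets <- names(vp$curves)
  ids <- atlas$region_names
  regions <- names(ids)[!grepl("^phantom", names(ids))]
  with_local_seed(design$seed, {
    subj_eff <- matrix(rlnorm_cov(design$n_subjects * length(mets),
                                  vp$between_subject_cov),
                       design$n_subjects, length(mets),
                       dimnames = list(NULL, mets))
    sess_eff <- array(rlnorm_cov(design$n_subjects * design$n_sessions *
                                   length(mets), vp$within_subject_cov),
                      c(design$n_subjects, design$n_sessions, length(mets)),
                      dimnames = list(NULL, NULL, mets))
    grid <- expand.grid(subject = seq_len(design$n_subjects),
                        session = seq_len(design$n_sessions),
                        timepoint_min = design$timepoints_min,
                        region = regions,
                        metabolite = mets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    curve_val <- function(met, t) {
      cf <- vp$curves[[met]]
      cf[1] * t + cf[2] * t^2
    }
    conc <- mapply(function(s, e, t, r, m) {
      base <- curve_val(m, t) * subj_eff[s, m] * sess_eff[s, e, m] *
        vp$regional_multipliers[[m]][[r]]
      if (t == 0) base <- 0
      if (m == "water") base <- base + vp$natural_abundance_mm
      base
    }, grid$subject, grid$session, grid$timepoint_min, grid$region,
       grid$metabolite)
    grid$conc_mm <- as.numeric(conc)
    grid
  })
}

#' Simulated B1 amplitude field
#'
#' Smooth radial quadratic, `1 + beta * (1 - 2 * r^2)` with `r` the
#' normalised distance from the grid center (`r = 1` at the corners): the
#' field is `1 + beta` at the center and `1 - beta` at the corners, i.e. a
#' peak-to-center span of `±beta`. Applied multiplicatively to signal
#' amplitudes (combined transmit-receive effect).
#'
#' @param grid_shape integer length-3.
#' @param beta fractional field amplitude for this exam.
#' @return 3D numeric array.
#' @export
b1_field <- function(grid_shape, beta) {
  co <- norm_coords(grid_shape)
  r2 <- outer(outer(co$x^2, co$y^2, "+"), co$z^2, "+") / 3
  1 + beta * (1 - 2 * r2)
}

#' Synthesize the raw CSI grid of one exam
#'
#' Each voxel's FID is the sum of the four damped complex exponentials
#' (frequencies and linewidths from the prior-knowledge table, amplitude =
#' local concentration x saturation factor x B1) plus i.i.d. complex
#' Gaussian noise of standard deviation `vp$noise_sd` per channel. Phantom
#' voxels contain only the water resonance at the nominal phantom
#' concentrations.
#'
#' @param truth_exam data.frame with columns `region`, `metabolite`,
#'   `conc_mm` for a single exam (one subject/session/timepoint).
#' @param atlas a `label_atlas`.
#' @param acq an [acq_params()].
#' @param vp a [variance_params()].
#' @param priors a [resonance_priors()] table.
#' @param seed integer noise seed.
#' @param beta B1 amplitude for this exam (0 = uniform field).
#' @param noiseless if `TRUE`, omit the additive noise (ground-truth FIDs).
#' @return a [spectral_grid()].
#' @export
synthesize_csi <- function(truth_exam, atlas, acq, vp, priors,
                           seed = 1L, beta = 0, noiseless = FALSE) {
  if (!all(truth_exam$region %in% names(atlas$region_names))) {
    stop("truth regions must be a subset of atlas regions")
  }
  mets <- priors$name
  shape <- dim(atlas$labels)
  nvox <- prod(shape)
  sat <- saturation_factor(acq$flip_deg, acq$tr_s, priors$t1_s)
  amps <- matrix(0, nvox, length(mets))
  ids <- atlas$region_names
  for (k in seq_along(mets)) {
    rows <- truth_exam[truth_exam$metabolite == mets[k], , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      amps[atlas$labels == ids[[rows$region[j]]], k] <- rows$conc_mm[j]
    }
  }
  iw <- match("water", mets)
  if (!is.na(iw)) {
    amps[atlas$labels == ids[["phantom_low"]], iw] <- vp$phantom_mm[[1]]
    amps[atlas$labels == ids[["phantom_high"]], iw] <- vp$phantom_mm[[2]]
  }
  amps <- amps * rep(sat, each = nvox) * as.vector(b1_field(shape, beta))
  lw <- if (is.null(vp$lw_true_hz)) priors$lw_init_hz else vp$lw_true_hz
  basis <- fid_basis(priors$freq_hz, pi * lw, time_axis(acq))
  fids <- amps %*% t(basis)
  if (!noiseless && vp$noise_sd > 0) {
    with_local_seed(seed, {
      fids <- fids + matrix(complex(
        real = stats::rnorm(nvox * acq$n_spectral, sd = vp$noise_sd),
        imaginary = stats::rnorm(nvox * acq$n_spectral, sd = vp$noise_sd)),
        nvox, acq$n_spectral)
    })
  }
  spectral_grid(array(fids, c(shape, acq$n_spectral)), acq, seed = seed)
}

#' Simulate a complete synthetic DMI study
#'
#' Draws the ground-truth concentration table, one B1 amplitude per
#' subject/session, and the raw CSI grid of every exam. Bit-identical for
#' identical `(design, vp, seed)`.
#'
#' @param design a [study_design()].
#' @param atlas a `label_atlas`; defaults to [make_atlas()] on `acq$matrix`.
#' @param acq an [acq_params()].
#' @param vp a [variance_params()].
#' @param priors a [resonance_priors()].
#' @return object of class `synthetic_study`: list with `design`, `atlas`,
#'   `acq`, `vp`, `priors`, `truth`, `exams` (data.frame with one row per
#'   exam: subject, session, timepoint_min, beta, seed, key) and `raw`
#'   (named list of `spectral_grid`s keyed as in `exams$key`).
#' @export
simulate_study <- function(design = study_design(),
                           acq = acq_params(),
                           atlas = make_atlas(acq$matrix,
                                              fov_mm = acq$fov_mm),
                           vp = variance_params(),
                           priors = resonance_priors(acq)) {
  truth <- sample_truth(design, atlas, vp)
  exams <- expand.grid(timepoint_min = design$timepoints_min,
                       session = seq_len(design$n_sessions),
                       subject = seq_len(design$n_subjects),
                       KEEP.OUT.ATTRS = FALSE)
  exams <- exams[, c("subject", "session", "timepoint_min")]
  betas <- with_local_seed(design$seed + 1L, {
    b <- expand.grid(session = seq_len(design$n_sessions),
                     subject = seq_len(design$n_subjects),
                     KEEP.OUT.ATTRS = FALSE)
    b$beta <- stats::runif(nrow(b), 0, vp$b1_amplitude_range)
    b
  })
  exams$beta <- betas$beta[match(
    paste(exams$subject, exams$session),
    paste(betas$subject, betas$session))]
  exams$seed <- (design$seed + 7919L * seq_len(nrow(exams))) %% 2147483647L
  exams$key <- sprintf("s%d_e%d_t%03d", exams$subject, exams$session,
                       exams$timepoint_min)
  raw <- vector("list", nrow(exams))
  names(raw) <- exams$key
  for (i in seq_len(nrow(exams))) {
    te <- truth[truth$subject == exams$subject[i] &
                  truth$session == exams$session[i] &
                  truth$timepoint_min == exams$timepoint_min[i], ]
    raw[[i]] <- synthesize_csi(te, atlas, acq, vp, priors,
                               seed = exams$seed[i], beta = exams$beta[i])
  }
  structure(list(design = design, atlas = atlas, acq = acq, vp = vp,
                 priors = priors, truth = truth, exams = exams, raw = raw),
            class = "synthetic_study")
}
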