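#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. The `"simple"`
#' processing variant reconstructs and fits the raw data directly; the
#' `"extended"` variant adds Marchenko-Pastur denoising before the fit and
#' Richardson-Lucy partial-volume plus bias-field correction after it
#' (denoise, then partial volume, then bias field).
#'
#' @param design a [study_design()].
#' @param acq an [acq_params()].
#' @param geometry an [atlas_geometry()].
#' @param vp a [variance_params()].
#' @param priors a [resonance_priors()].
#' @param corrections a [correction_config()]; defaults are derived from
#'   `acq` and `priors` so simulator and correction share one T1 table.
#' @param qc a [qc_rule()].
#' @param variant `"extended"` (default) or `"simple"`.
#' @param modes quantification modes to report, subset of
#'   `c("baseline", "cerebellum", "phantom")`.
#' @param denoise a [patch_config()].
#' @param rl_iterations Richardson-Lucy iteration count.
#' @param bias_order polynomial order of the bias-field model.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(),
                            acq = acq_params(),
                            geometry = atlas_geometry(),
                            vp = variance_params(),
                            priors = resonance_priors(acq),
                            corrections = NULL,
                            qc = qc_rule(),
                            variant = c("extended", "simple"),
                            modes = c("baseline", "cerebellum", "phantom"),
                            denoise = patch_config(),
                            rl_iterations = 10L,
                            bias_order = 2L,
                            out_dir = NULL) {
  variant <- match.arg(variant)
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(corrections)) {
    corrections <- correction_config(
      t1_s = stats::setNames(priors$t1_s, priors$name),
      flip_deg = acq$flip_deg, tr_s = acq$tr_s,
      natural_abundance_hdo_mm = vp$natural_abundance_mm,
      phantom_concentrations_mm = as.numeric(vp$phantom_mm))
  }
  structure(list(design = design, acq = acq, geometry = geometry, vp = vp,
                 priors = priors, corrections = corrections, qc = qc,
                 variant = variant, modes = modes, denoise = denoise,
                 rl_iterations = as.integer(rl_iterations),
                 bias_order = as.integer(bias_order), out_dir = out_dir),
            class = "pipeline_config")
}

# water SNR / linewidth of every masked voxel from the raw spectra
# (vectorised FFT; the "pre-processing" QC metrics)
water_qc_metrics <- function(grid, mask, window_hz = 20) {
  acq <- grid$acq
  dims <- dim(grid$data)[1:3]
  nt <- dim(grid$data)[4]
  vox <- which(mask)
  fids <- t(matrix(grid$data, prod(dims), nt)[vox, , drop = FALSE])
  nfft <- nt * 4L
  padded <- rbind(fids, matrix(0 + 0i, nfft - nt, length(vox)))
  sp <- stats::mvfft(padded)
  half <- ceiling(nfft / 2)
  sp <- sp[c((half + 1):nfft, 1:half), , drop = FALSE]
  freq <- (c((half - nfft):(-1), 0:(half - 1))) * acq$bandwidth_hz / nfft
  edge <- 0.1 * (max(freq) - min(freq))
  in_noise <- freq <= min(freq) + edge | freq >= max(freq) - edge
  in_peak <- freq >= -window_hz & freq <= window_hz
  noise_sd <- apply(Re(sp[in_noise, , drop = FALSE]), 2, stats::sd)
  mag <- Mod(sp[in_peak, , drop = FALSE])
  pk <- apply(mag, 2, max)
  fwhm <- vapply(seq_along(vox), function(j) {
    m <- Mod(sp[, j])
    ipk <- which(in_peak)[which.max(mag[, j])]
    fwhm_interp(freq, m, ipk) / sqrt(3)  # magnitude -> absorption scale
  }, numeric(1))
  data.frame(voxel = vox, water_snr = pk / noise_sd, water_fwhm_hz = fwhm)
}

# process one exam grid into corrected amplitude maps (arbitrary units);
# a baseline exam contains only the natural-abundance water signal, so only
# the water resonance is fitted there (it is purely the quantification
# reference)
process_exam <- function(grid, atlas, config, baseline = FALSE) {
  bmask <- brain_mask(atlas)
  pmask <- array(atlas$labels %in%
                   atlas$region_names[c("phantom_low", "phantom_high")],
                 dim(atlas$labels))
  qcm <- water_qc_metrics(grid, bmask)
  qres <- qc_mask(qcm, config$qc)
  keep <- array(FALSE, dim(atlas$labels))
  keep[qcm$voxel[qres$retained & !is.na(qres$retained)]] <- TRUE
  work <- grid
  if (config$variant == "extended") {
    work <- denoise_grid(work, config$denoise)
  }
  priors <- config$priors
  if (baseline) priors <- priors[priors$name == "water", , drop = FALSE]
  fit <- fit_grid(work, priors, mask = keep | pmask)
  maps <- lapply(priors$name, function(met) {
    vol <- fit_map(fit, met, "amplitude")
    vol[is.na(vol)] <- 0
    metabolite_map(vol, met, units = "au",
                   mask = if (met == "water") keep | pmask else keep,
                   provenance = paste0("fit:", config$variant))
  })
  names(maps) <- priors$name
  if (config$variant == "extended") {
    psf <- psf_gaussian()
    field <- NULL
    wvals <- maps$water$values
    if (sum(keep) > 20) {
      # estimate the multiplicative bias field once, from water, and share it
      corrected_w <- bias_field_correct(wvals, mask = keep & wvals > 0,
                                        order = config$bias_order)
      field <- wvals / pmax(corrected_w, .Machine$double.eps)
      field[!(keep & wvals > 0)] <- 1
    }
    maps <- lapply(maps, function(mp) {
      mp <- partial_volume_correct(mp, psf, n_iter = config$rl_iterations)
      if (!is.null(field)) {
        before <- mean(mp$values[mp$mask])
        mp$values <- mp$values / field
        after <- mean(mp$values[mp$mask])
        if (is.finite(before) && is.finite(after) && after > 0) {
          mp$values <- mp$values * before / after
        }
        mp <- add_provenance(mp, "bias_field_correct(shared water field)")
      }
      mp
    })
  }
  maps <- lapply(maps, saturation_correct, cfg = config$corrections)
  list(maps = maps, qc = qcm, n_excluded = qres$n_excluded, fit = fit)
}

#' Run the full simulate-process-quantify-statistics pipeline
#'
#' Simulates every exam of the configured study, processes each with the
#' selected variant, quantifies with each requested normalization mode,
#' aggregates regional means, and computes the repeatability tables.
#' Exams are synthesized and processed one at a time (streaming), so the
#' full study never needs to be held in memory. Deterministic: the same
#' configuration (including `design$seed`) reproduces every table.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-exam progress.
#' @return object of class `dmi_pipeline_result`: list with `regional`
#'   (long data.frame: subject, session, timepoint_min, region, metabolite,
#'   value, units, mode, n_voxels), `repeatability` (named list of
#'   [repeatability_table()]s per mode), `qc` (per-exam exclusion counts),
#'   `truth`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  atlas <- make_atlas(config$acq$matrix, config$geometry, config$acq$fov_mm)
  truth <- sample_truth(design, atlas, config$vp)
  exams <- expand.grid(timepoint_min = design$timepoints_min,
                       session = seq_len(design$n_sessions),
                       subject = seq_len(design$n_subjects),
                       KEEP.OUT.ATTRS = FALSE)
  betas <- with_local_seed(design$seed + 1L, {
    b <- expand.grid(session = seq_len(design$n_sessions),
                     subject = seq_len(design$n_subjects),
                     KEEP.OUT.ATTRS = FALSE)
    b$beta <- stats::runif(nrow(b), 0, config$vp$b1_amplitude_range)
    b
  })
  exams$beta <- betas$beta[match(paste(exams$subject, exams$session),
                                 paste(betas$subject, betas$session))]
  exams$seed <- (design$seed + 7919L * seq_len(nrow(exams))) %% 2147483647L

  regional_rows <- list()
  qc_rows <- list()
  baseline_water <- list()
  mets <- config$priors$name

  for (i in seq_len(nrow(exams))) {
    ex <- exams[i, ]
    if (verbose) {
      message(sprintf("exam %d/%d: subject %d session %d t=%d min",
                      i, nrow(exams), ex$subject, ex$session,
                      ex$timepoint_min))
    }
    te <- truth[truth$subject == ex$subject & truth$session == ex$session &
                  truth$timepoint_min == ex$timepoint_min, ]
    grid <- synthesize_csi(te, atlas, config$acq, config$vp, config$priors,
                           seed = ex$seed, beta = ex$beta)
    proc <- tryCatch(
      process_exam(grid, atlas, config, baseline = ex$timepoint_min == 0),
      error = function(e) {
        stop(sprintf("stage 'process' failed for subject %d session %d t=%d: %s",
                     ex$subject, ex$session, ex$timepoint_min,
                     conditionMessage(e)), call. = FALSE)
      })
    qc_rows[[i]] <- data.frame(subject = ex$subject, session = ex$session,
                               timepoint_min = ex$timepoint_min,
                               n_excluded = proc$n_excluded)
    skey <- paste(ex$subject, ex$session)
    if (ex$timepoint_min == 0) {
      # the baseline exam only provides the water reference map
      baseline_water[[skey]] <- proc$maps$water
      next
    }
    for (mode in config$modes) {
      if (mode == "baseline" && is.null(baseline_water[[skey]])) next
      qmaps <- lapply(mets, function(met) {
        # a degenerate reference (e.g. zero metabolite mean in a tiny
        # cerebellum) makes this exam's metabolite missing, not fatal
        tryCatch(
          quantify(proc$maps[[met]], mode = mode, atlas = atlas,
                   cfg = config$corrections,
                   baseline_water = baseline_water[[skey]],
                   water_map = proc$maps$water),
          error = function(e) NULL)
      })
      names(qmaps) <- mets
      for (met in mets) {
        if (is.null(qmaps[[met]])) next
        rm_ <- regional_means(qmaps[[met]], atlas)
        rm_$subject <- ex$subject
        rm_$session <- ex$session
        rm_$timepoint_min <- ex$timepoint_min
        rm_$metabolite <- met
        rm_$units <- qmaps[[met]]$units
        rm_$mode <- mode
        regional_rows[[length(regional_rows) + 1L]] <- rm_
      }
    }
  }
  regional <- do.call(rbind, regional_rows)
  regional <- regional[, c("subject", "session", "timepoint_min", "region",
                           "metabolite", "mean", "units", "mode",
                           "n_voxels")]
  names(regional)[names(regional) == "mean"] <- "value"

  repeat_tabs <- lapply(config$modes, function(mode) {
    sub <- regional[regional$mode == mode & regional$timepoint_min > 0 &
                      is.finite(regional$value), ]
    repeatability_table(sub)
  })
  names(repeat_tabs) <- config$modes

  manifest <- list(
    package = "dmirep",
    version = as.character(utils::packageVersion("dmirep")),
    seed = design$seed,
    variant = config$variant,
    modes = config$modes,
    design = list(n_subjects = design$n_subjects,
                  n_sessions = design$n_sessions,
                  timepoints_min = design$timepoints_min),
    acquisition = list(matrix = config$acq$matrix,
                       n_spectral = config$acq$n_spectral,
                       bandwidth_hz = config$acq$bandwidth_hz),
    variance = list(between_subject_cov = config$vp$between_subject_cov,
                    within_subject_cov = config$vp$within_subject_cov,
                    noise_sd = config$vp$noise_sd,
                    b1_amplitude_range = config$vp$b1_amplitude_range)
  )
  result <- structure(list(regional = regional,
                           repeatability = repeat_tabs,
                           qc = do.call(rbind, qc_rows),
                           truth = truth, atlas = atlas,
                           config = config, manifest = manifest),
                      class = "dmi_pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(regional, file.path(config$out_dir, "regional.csv"),
                     row.names = FALSE)
    for (mode in config$modes) {
      utils::write.csv(repeat_tabs[[mode]],
                       file.path(config$out_dir,
                                 sprintf("repeatability_%s.csv", mode)),
                       row.names = FALSE)
    }
    utils::write.csv(result$qc, file.path(config$out_dir, "qc.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.dmi_pipeline_result <- function(x, ...) {
  cat("DMI pipeline result (", x$config$variant, " variant)\n", sep = "")
  cat("exams:", nrow(x$qc), " mean excluded voxels:",
      round(mean(x$qc$n_excluded), 2), "\n")
  for (mode in names(x$repeatability)) {
    tab <- x$repeatability[[mode]]
    wb <- tab[tab$region == "whole_brain", ]
    cat("\nmode ", mode, " (whole brain):\n", sep = "")
    print(wb[, c("metabolite", "timepoint", "within_subject_cov_pct",
                 "repeatability_coefficient_pct",
                 "between_subject_cov_pct")], row.names = FALSE)
  }
  invisible(x)
}
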