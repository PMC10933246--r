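#' Fit all voxels of a CSI grid
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with an analytic
#' Jacobian, box constraints by projection) of the sum-of-Lorentzians model
#' of [fid_model()] to every selected voxel, in the time domain on the
#' stacked real/imaginary residuals. One zero-order phase is shared by all
#' resonances; relative phases are fixed at 0 and no first-order phase is
#' fitted. Starting amplitudes come from a linear least-squares projection
#' of the FID onto the prior basis; frequencies and linewidths start at the
#' prior values. Amplitudes are bounded below by 0, frequencies by the
#' prior window, linewidths by the prior range. A voxel that fails to
#' converge (or is identically zero) is flagged, never an error.
#'
#' Per-resonance SNR is reported on the spectral scale: fitted amplitude
#' times the closed-form Lorentzian peak gain, divided by the spectral
#' noise standard deviation implied by the FID-tail noise estimate
#' (`sigma_tail * sqrt(N)`). A time-domain variant
#' (`amplitude / sigma_tail`) is available via `snr_source`.
#'
#' @param grid a [spectral_grid()].
#' @param priors a [resonance_priors()] table.
#' @param mask optional logical 3D array of voxels to fit (default: all).
#' @param noise_sd optional known per-channel noise sd used for the CRLB%;
#'   default uses the per-voxel FID-tail estimate.
#' @param snr_source `"spectral"` (default) or `"time_domain"`.
#' @param max_iter,tol optimizer controls.
#' @return object of class `dmi_fit`: matrices `amplitude`,
#'   `frequency_hz`, `damping`, `lw_hz`, `crlb_percent`, `snr` (voxel x
#'   resonance), vectors `phase_rad`, `sigma_tail`, `residual`,
#'   `converged`, `iterations`, plus `voxel_index`, `dims`, `priors`,
#'   `acq`.
#' @export
fit_grid <- function(grid, priors, mask = NULL, noise_sd = NULL,
                     snr_source = c("spectral", "time_domain"),
                     max_iter = 500L, tol = 1e-10) {
  snr_source <- match.arg(snr_source)
  acq <- grid$acq
  dims <- dim(grid$data)[1:3]
  nt <- dim(grid$data)[4]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(all(dim(mask) == dims))
  vox <- which(mask)
  if (length(vox) == 0L) stop("empty mask")
  fids <- t(matrix(grid$data, prod(dims), nt)[vox, , drop = FALSE])
  k <- nrow(priors)
  d0 <- pi * priors$lw_init_hz
  lb <- c(rep(0, k), priors$freq_hz - priors$freq_bound_hz,
          rep(pi * priors$lw_min_hz[1], k), -pi)
  ub <- c(rep(Inf, k), priors$freq_hz + priors$freq_bound_hz,
          rep(pi * priors$lw_max_hz[1], k), pi)
  res <- fit_fids_cpp(fids, time_axis(acq), priors$freq_hz, d0, lb, ub,
                      as.integer(max_iter), tol, 0.1)
  res$sigma_tail <- as.numeric(res$sigma_tail)
  res$phase_rad <- as.numeric(res$phase_rad)
  res$residual <- as.numeric(res$residual)
  res$initial_residual <- as.numeric(res$initial_residual)
  sig <- if (is.null(noise_sd)) res$sigma_tail else rep(noise_sd,
                                                        length(vox))
  amp <- res$amplitude
  crlb_pct <- 100 * res$crlb_unit * sig / pmax(amp, .Machine$double.eps)
  crlb_pct[amp <= 0] <- Inf
  dt <- 1 / acq$bandwidth_hz
  gain <- vapply(seq_len(k), function(j)
    lorentz_peak_gain(res$damping[, j], dt, nt), numeric(length(vox)))
  gain <- matrix(gain, nrow = length(vox))
  snr <- if (snr_source == "spectral") {
    amp * gain / (pmax(sig, .Machine$double.eps) * sqrt(nt))
  } else {
    amp / pmax(sig, .Machine$double.eps)
  }
  structure(list(amplitude = amp, frequency_hz = res$frequency_hz,
                 damping = res$damping, lw_hz = res$damping / pi,
                 crlb_percent = crlb_pct, snr = snr,
                 crlb_unit = res$crlb_unit,
                 phase_rad = as.numeric(res$phase_rad),
                 sigma_tail = as.numeric(res$sigma_tail),
                 residual = as.numeric(res$residual),
                 initial_residual = as.numeric(res$initial_residual),
                 converged = as.logical(res$converged),
                 iterations = as.integer(res$iterations),
                 voxel_index = vox, dims = dims,
                 resonances = priors$name, priors = priors, acq = acq,
                 snr_source = snr_source),
            class = "dmi_fit")
}

#' Fit a single FID
#'
#' Convenience wrapper around [fit_grid()] for one voxel.
#'
#' @param fid complex FID vector of length `acq$n_spectral`.
#' @param priors a [resonance_priors()] table.
#' @param acq an [acq_params()].
#' @param ... passed to [fit_grid()].
#' @return object of class `fit_result`: list with a per-resonance
#'   data.frame `resonances` (amplitude, frequency_hz, lw_hz, damping,
#'   crlb_percent, snr), shared `phase_rad`, `sigma_tail`, `residual` and
#'   `converged`.
#' @export
fit_voxel <- function(fid, priors, acq, ...) {
  if (any(!is.finite(Re(fid))) || any(!is.finite(Im(fid)))) {
    stop("FID must be finite")
  }
  acq1 <- acq
  acq1$matrix <- c(1L, 1L, 1L)
  grid <- spectral_grid(array(fid, c(1, 1, 1, length(fid))), acq1)
  fg <- fit_grid(grid, priors, ...)
  structure(list(
    resonances = data.frame(name = fg$resonances,
                            amplitude = fg$amplitude[1, ],
                            frequency_hz = fg$frequency_hz[1, ],
                            damping = fg$damping[1, ],
                            lw_hz = fg$lw_hz[1, ],
                            crlb_percent = fg$crlb_percent[1, ],
                            snr = fg$snr[1, ],
                            stringsAsFactors = FALSE),
    phase_rad = fg$phase_rad[1], sigma_tail = fg$sigma_tail[1],
    residual = fg$residual[1],
    initial_residual = fg$initial_residual[1],
    converged = fg$converged[1], crlb_unit = fg$crlb_unit[1, ],
    acq = acq), class = "fit_result")
}

#' Cramer-Rao lower bound as percent of amplitude
#'
#' CRLB from the inverse Fisher information of the time-domain model at the
#' fitted parameters, for a given noise level:
#' `100 * sqrt(var_min(amplitude)) / amplitude`, linear in `noise_sd`.
#'
#' @param fit a `fit_result` from [fit_voxel()].
#' @param noise_sd per-channel (real/imaginary) noise standard deviation.
#' @return named numeric vector, one CRLB% per resonance (Inf where the
#'   information matrix is singular or the amplitude is zero).
#' @export
crlb_percent <- function(fit, noise_sd) {
  stopifnot(inherits(fit, "fit_result"), noise_sd > 0)
  if (!isTRUE(fit$converged)) {
    warning("CRLB requested for a non-converged fit")
  }
  a <- fit$resonances$amplitude
  out <- 100 * fit$crlb_unit * noise_sd / pmax(a, .Machine$double.eps)
  out[a <= 0] <- Inf
  stats::setNames(out, fit$resonances$name)
}

#' Voxel quality-control rule
#'
#' Voxels are retained only if the water SNR exceeds `water_snr_min`
#' (strictly) and the water linewidth does not exceed
#' `water_linewidth_max_hz`.
#'
#' @param water_snr_min minimum water SNR (default 5).
#' @param water_linewidth_max_hz maximum water FWHM in Hz (default 30).
#' @return object of class `qc_rule`.
#' @export
qc_rule <- function(water_snr_min = 5, water_linewidth_max_hz = 30) {
  stopifnot(water_snr_min >= 0, water_linewidth_max_hz > 0)
  structure(list(water_snr_min = water_snr_min,
                 water_linewidth_max_hz = water_linewidth_max_hz),
            class = "qc_rule")
}

#' Apply the voxel QC rule
#'
#' Accepts either a `dmi_fit` (water metrics are taken from the fitted
#' water resonance) or a data.frame with columns `water_snr` and
#' `water_fwhm_hz`. A voxel is retained iff `water_snr > water_snr_min`
#' and `water_fwhm_hz <= water_linewidth_max_hz` (and, for fits, the voxel
#' converged).
#'
#' @param x a `dmi_fit` or a data.frame.
#' @param rule a [qc_rule()].
#' @return list with logical `retained` (per fitted voxel / row),
#'   `n_excluded`, and for fits a 3D logical `mask` over the grid.
#' @export
qc_mask <- function(x, rule = qc_rule()) {
  if (is.data.frame(x)) {
    keep <- x$water_snr > rule$water_snr_min &
      x$water_fwhm_hz <= rule$water_linewidth_max_hz
    return(list(retained = keep, n_excluded = sum(!keep)))
  }
  stopifnot(inherits(x, "dmi_fit"))
  iw <- match("water", x$resonances)
  if (is.na(iw)) stop("no water resonance in fit")
  keep <- x$converged & x$snr[, iw] > rule$water_snr_min &
    x$lw_hz[, iw] <= rule$water_linewidth_max_hz
  mask <- array(FALSE, x$dims)
  mask[x$voxel_index[keep]] <- TRUE
  list(retained = keep, n_excluded = sum(!keep), mask = mask)
}

#' Extract a 3D parameter map from a grid fit
#'
#' @param fit a `dmi_fit`.
#' @param metabolite resonance name.
#' @param what one of `"amplitude"`, `"frequency_hz"`, `"lw_hz"`,
#'   `"crlb_percent"`, `"snr"`.
#' @return 3D numeric array, `NA` outside the fitted voxels.
#' @export
fit_map <- function(fit, metabolite, what = "amplitude") {
  stopifnot(inherits(fit, "dmi_fit"))
  j <- match(metabolite, fit$resonances)
  if (is.na(j)) stop("unknown resonance: ", metabolite)
  vals <- fit[[what]][, j]
  out <- array(NA_real_, fit$dims)
  out[fit$voxel_index] <- vals
  out
}

#' Tidy per-voxel fit table
#'
#' @param x a `dmi_fit`.
#' @param ... unused.
#' @return data.frame with one row per voxel and resonance (voxel index,
#'   resonance, amplitude, frequency_hz, lw_hz, crlb_percent, snr,
#'   converged).
#' @export
as.data.frame.dmi_fit <- function(x, ...) {
  nv <- length(x$voxel_index)
  k <- length(x$resonances)
  data.frame(
    voxel = rep(x$voxel_index, times = k),
    resonance = rep(x$resonances, each = nv),
    amplitude = as.vector(x$amplitude),
    frequency_hz = as.vector(x$frequency_hz),
    lw_hz = as.vector(x$lw_hz),
    crlb_percent = as.vector(x$crlb_percent),
    snr = as.vector(x$snr),
    converged = rep(x$converged, times = k),
    stringsAsFactors = FALSE
  )
}
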