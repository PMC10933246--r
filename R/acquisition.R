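#' Acquisition parameters for a chemical-shift-imaging exam
#'
#' Bundles the constants of a 3D CSI deuterium acquisition: spatial matrix,
#' field of view, number of spectral points, spectral bandwidth, excitation
#' flip angle, repetition time and the deuterium Larmor frequency used to
#' convert between Hz and ppm. Defaults correspond to a clinical 3-T brain
#' protocol (10x10x10 matrix over a 240 mm FOV, 700 points at 5000 Hz,
#' 70 degree flip, TR 155.8 ms, 19.6 MHz for deuterium at 3 T).
#'
#' @param matrix integer vector of length 3, spatial matrix size.
#' @param fov_mm numeric vector of length 3, field of view in mm.
#' @param n_spectral number of complex FID points per voxel.
#' @param bandwidth_hz spectral (sampling) bandwidth in Hz.
#' @param flip_deg excitation flip angle in degrees, in (0, 180].
#' @param tr_s repetition time in seconds.
#' @param larmor_mhz Larmor frequency in MHz (1 ppm = `larmor_mhz` Hz).
#' @param water_ppm chemical shift assigned to the water resonance; the
#'   frequency axis is referenced so that water sits at 0 Hz.
#'
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(matrix = c(10L, 10L, 10L),
                       fov_mm = c(240, 240, 240),
                       n_spectral = 700L,
                       bandwidth_hz = 5000,
                       flip_deg = 70,
                       tr_s = 0.1558,
                       larmor_mhz = 19.6,
                       water_ppm = 4.8) {
  matrix <- as.integer(matrix)
  stopifnot(length(matrix) == 3L, all(matrix >= 1L),
            length(fov_mm) == 3L, all(fov_mm > 0),
            n_spectral >= 2L, bandwidth_hz > 0,
            flip_deg > 0, flip_deg <= 180, tr_s > 0, larmor_mhz > 0)
  structure(list(matrix = matrix, fov_mm = as.numeric(fov_mm),
                 n_spectral = as.integer(n_spectral),
                 bandwidth_hz = bandwidth_hz, flip_deg = flip_deg,
                 tr_s = tr_s, larmor_mhz = larmor_mhz,
                 water_ppm = water_ppm),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("CSI acquisition: ", paste(x$matrix, collapse = "x"),
      " voxels, ", x$n_spectral, " pts @ ", x$bandwidth_hz, " Hz, flip ",
      x$flip_deg, " deg, TR ", x$tr_s * 1000, " ms\n", sep = "")
  invisible(x)
}

#' FID time axis
#'
#' @param acq an [acq_params()] object.
#' @return numeric vector of sampling times in seconds, starting at 0.
#' @export
time_axis <- function(acq) {
  (seq_len(acq$n_spectral) - 1) / acq$bandwidth_hz
}

#' Prior knowledge for the deuterium resonances
#'
#' Returns the prior-knowledge table used to constrain the time-domain fit:
#' one row per resonance with its chemical shift, its frequency offset
#' relative to water, a symmetric frequency search bound, the initial
#' linewidth (Lorentzian FWHM) with its allowed range, and the longitudinal
#' relaxation time used for the saturation correction. Chemical shifts and
#' T1 values are literature defaults and fully overridable; nothing
#' downstream hard-codes them.
#'
#' @param acq an [acq_params()] object (sets the Hz-per-ppm conversion).
#' @param ppm chemical shifts of the resonances.
#' @param names resonance names.
#' @param lw_init_hz initial linewidths (FWHM, Hz).
#' @param lw_bounds_hz length-2 numeric, allowed linewidth range (FWHM, Hz).
#' @param freq_bound_ppm half-width of the frequency search window in ppm.
#' @param t1_s longitudinal relaxation times in seconds.
#'
#' @return data.frame of class `resonance_priors` with columns `name`,
#'   `ppm`, `freq_hz` (offset from water), `freq_bound_hz`, `lw_init_hz`,
#'   `lw_min_hz`, `lw_max_hz`, `t1_s`.
#' @export
resonance_priors <- function(acq = acq_params(),
                             ppm = c(4.8, 3.8, 2.4, 1.3),
                             names = c("water", "glucose", "glx", "lactate"),
                             lw_init_hz = c(10, 10, 15, 26),
                             lw_bounds_hz = c(1, 50),
                             freq_bound_ppm = 0.3,
                             t1_s = c(0.320, 0.064, 0.146, 0.297)) {
  stopifnot(length(ppm) == length(names), length(lw_init_hz) == length(ppm),
            length(t1_s) == length(ppm), length(lw_bounds_hz) == 2L,
            lw_bounds_hz[1] > 0, diff(lw_bounds_hz) > 0,
            all(lw_init_hz >= lw_bounds_hz[1]),
            all(lw_init_hz <= lw_bounds_hz[2]),
            freq_bound_ppm > 0, all(t1_s > 0))
  out <- data.frame(
    name = names,
    ppm = ppm,
    freq_hz = (ppm - acq$water_ppm) * acq$larmor_mhz,
    freq_bound_hz = freq_bound_ppm * acq$larmor_mhz,
    lw_init_hz = lw_init_hz,
    lw_min_hz = lw_bounds_hz[1],
    lw_max_hz = lw_bounds_hz[2],
    t1_s = t1_s,
    stringsAsFactors = FALSE
  )
  class(out) <- c("resonance_priors", "data.frame")
  out
}

#' Steady-state partial saturation factor
#'
#' Signal attenuation of a spoiled steady-state acquisition with repetition
#' time short relative to T1: `s = sin(a) * (1 - E1) / (1 - cos(a) * E1)`
#' with `E1 = exp(-TR / T1)`. Fitted amplitudes are divided by this factor
#' to correct for partial radiofrequency saturation.
#'
#' @param flip_deg flip angle in degrees (> 0).
#' @param tr_s repetition time in seconds.
#' @param t1_s longitudinal relaxation time in seconds (vectorised).
#' @return saturation factor(s) in (0, 1].
#' @export
saturation_factor <- function(flip_deg, tr_s, t1_s) {
  stopifnot(flip_deg > 0, flip_deg <= 180, tr_s > 0, all(t1_s > 0))
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_s / t1_s)
  s <- sin(a) * (1 - e1) / (1 - cos(a) * e1)
  if (any(s <= 0)) stop("saturation factor is non-positive")
  s
}
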