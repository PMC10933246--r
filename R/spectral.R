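#' Damped complex-exponential FID model
#'
#' Evaluates the sum-of-Lorentzians time-domain model
#' `sum_k a_k * exp(i phi_k) * exp((2 pi i f_k - d_k) * t)`,
#' the signal model underlying both the simulator and the fit. Dampings are
#' exponential decay rates `d` in 1/s; the corresponding Lorentzian
#' linewidth is `FWHM = d / pi` Hz.
#'
#' @param amplitudes,frequencies_hz,dampings_hz,phases_rad equal-length
#'   numeric parameter vectors (one entry per resonance); dampings must be
#'   non-negative.
#' @param time_axis sampling times in seconds.
#' @return complex vector of length `length(time_axis)`.
#' @export
fid_model <- function(amplitudes, frequencies_hz, dampings_hz, phases_rad,
                      time_axis) {
  k <- length(amplitudes)
  if (length(frequencies_hz) != k || length(dampings_hz) != k ||
      length(phases_rad) != k) {
    stop("parameter vectors must have equal length")
  }
  if (any(dampings_hz < 0)) stop("dampings must be >= 0")
  basis <- fid_basis(frequencies_hz, dampings_hz, time_axis)
  drop(basis %*% (amplitudes * exp(1i * phases_rad)))
}

# time x resonance matrix of unit-amplitude, zero-phase components
fid_basis <- function(frequencies_hz, dampings_hz, time_axis) {
  z <- outer(time_axis, 2i * pi * frequencies_hz - dampings_hz)
  exp(z)
}

#' Closed-form spectral peak gain of a sampled Lorentzian
#'
#' Height of the on-resonance (unnormalised) FFT peak of a unit-amplitude
#' exponentially damped FID: `sum_{j=0}^{n-1} exp(-d j dt)`. Used to
#' convert fitted time-domain amplitudes to spectral peak heights (and
#' hence spectral SNR) without reconstructing a spectrum.
#'
#' @param damping_hz exponential damping rate `d` in 1/s (FWHM = d/pi).
#' @param dt dwell time in seconds (1 / bandwidth).
#' @param n number of sampled FID points.
#' @return the dimensionless peak gain.
#' @export
lorentz_peak_gain <- function(damping_hz, dt, n) {
  e <- exp(-damping_hz * dt)
  ifelse(damping_hz <= 0, n, (1 - e^n) / (1 - e))
}

#' 4D complex CSI container
#'
#' A `spectral_grid` holds the raw (or processed) free-induction decays of a
#' whole CSI exam as a 4D complex array (x, y, z, time) together with its
#' acquisition parameters. It is the unit of exchange between the
#' reconstruction, denoising and fitting stages.
#'
#' @param data 4D complex array; the 4th dimension is time and must equal
#'   `acq$n_spectral`, the first three must equal `acq$matrix`.
#' @param acq an [acq_params()] object.
#' @param seed optional integer recorded for provenance.
#' @return object of class `spectral_grid`.
#' @export
spectral_grid <- function(data, acq, seed = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (!all(dim(data)[1:3] == acq$matrix) ||
      dim(data)[4] != acq$n_spectral) {
    stop("data dimensions do not match acquisition parameters")
  }
  if (!is.complex(data)) storage.mode(data) <- "complex"
  structure(list(data = data, acq = acq, seed = seed),
            class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat("spectral_grid: ", paste(dim(x$data)[1:3], collapse = "x"),
      " voxels x ", dim(x$data)[4], " points\n", sep = "")
  invisible(x)
}

#' Reconstruct a spectrum from an FID
#'
#' Fast Fourier transform without apodization ("no line broadening"),
#' preceded by zero filling. `zero_fill_doublings = 2` reads the
#' conventional "zero filled twice" as two successive doublings of the
#' record length (700 -> 2800 points); `mode = "append"` instead appends
#' twice the original length (700 -> 2100).
#'
#' @param fid complex vector of raw FID samples.
#' @param acq an [acq_params()] object (frequency axis metadata).
#' @param zero_fill_doublings non-negative integer count of length doublings.
#' @param mode `"doubling"` (default) or `"append"`.
#' @return object of class `dmi_spectrum`: list with complex `values`,
#'   `freq_hz` (offset from water, ascending), `ppm`, `n_original`,
#'   `zero_fill` and `acq`.
#' @export
reconstruct_spectrum <- function(fid, acq, zero_fill_doublings = 2L,
                                 mode = c("doubling", "append")) {
  mode <- match.arg(mode)
  n0 <- length(fid)
  if (n0 == 0L) stop("empty FID")
  zero_fill_doublings <- as.integer(zero_fill_doublings)
  stopifnot(zero_fill_doublings >= 0L)
  n <- if (mode == "doubling") n0 * 2L^zero_fill_doublings
       else n0 * (1L + zero_fill_doublings)
  padded <- c(fid, complex(real = rep(0, n - n0)))
  sp <- stats::fft(padded)
  # fftshift so the axis runs from -bw/2 to +bw/2 (water offset at 0 Hz)
  half <- ceiling(n / 2)
  idx <- c((half + 1):n, 1:half)
  bins <- c((half - n):(-1), 0:(half - 1))
  freq_hz <- bins * acq$bandwidth_hz / n
  structure(list(values = sp[idx], freq_hz = freq_hz,
                 ppm = acq$water_ppm + freq_hz / acq$larmor_mhz,
                 n_original = n0, zero_fill = zero_fill_doublings,
                 mode = mode, acq = acq),
            class = "dmi_spectrum")
}

#' Spectrum SNR and linewidth
#'
#' SNR is the maximum magnitude inside the peak window divided by the
#' standard deviation of the real part inside the noise window. The
#' linewidth is measured as the full width at half maximum of the
#' magnitude peak (half-maximum crossings, linear interpolation between
#' frequency samples) and converted to the equivalent Lorentzian
#' absorption FWHM by dividing by `sqrt(3)` (the magnitude profile of a
#' Lorentzian is `sqrt(3)` times wider than its absorption profile), so
#' reported values are on the conventional linewidth scale `damping / pi`.
#'
#' @param spectrum a `dmi_spectrum`.
#' @param peak_window,length-2 numeric ranges in Hz (offset from water);
#'   must not overlap. `noise_window` defaults to the outer 10% of both
#'   spectral edges (metabolite-free by construction).
#' @param noise_window length-2 numeric or `NULL` for the default edges.
#' @return named list `snr`, `fwhm_hz`, `peak_hz` (location of the maximum),
#'   `noise_sd`.
#' @export
spectrum_metrics <- function(spectrum, peak_window, noise_window = NULL) {
  f <- spectrum$freq_hz
  mag <- Mod(spectrum$values)
  stopifnot(length(peak_window) == 2L)
  peak_window <- sort(peak_window)
  if (is.null(noise_window)) {
    edge <- 0.1 * (max(f) - min(f))
    in_noise <- f <= min(f) + edge | f >= max(f) - edge
  } else {
    noise_window <- sort(noise_window)
    if (noise_window[1] < min(f) || noise_window[2] > max(f)) {
      stop("noise window outside the frequency axis")
    }
    if (noise_window[1] < peak_window[2] && noise_window[2] > peak_window[1]) {
      stop("peak and noise windows overlap")
    }
    in_noise <- f >= noise_window[1] & f <= noise_window[2]
  }
  in_peak <- f >= peak_window[1] & f <= peak_window[2]
  if (!any(in_peak)) stop("peak window outside the frequency axis")
  noise_sd <- stats::sd(Re(spectrum$values[in_noise]))
  if (!is.finite(noise_sd) || noise_sd == 0) {
    stop("noise window has zero variance; SNR undefined")
  }
  ipk <- which(in_peak)[which.max(mag[in_peak])]
  peak <- mag[ipk]
  list(snr = peak / noise_sd,
       fwhm_hz = fwhm_interp(f, mag, ipk) / sqrt(3),
       peak_hz = f[ipk],
       noise_sd = noise_sd)
}

# FWHM by linear interpolation of the half-maximum crossings around index ipk
fwhm_interp <- function(f, mag, ipk) {
  half <- mag[ipk] / 2
  n <- length(mag)
  cross <- function(dir) {
    i <- ipk
    while (i + dir >= 1 && i + dir <= n && mag[i + dir] > half) i <- i + dir
    j <- i + dir
    if (j < 1 || j > n) return(NA_real_)
    # interpolate between samples i (above half) and j (at or below half)
    f[i] + (f[j] - f[i]) * (mag[i] - half) / (mag[i] - mag[j])
  }
  lo <- cross(-1L)
  hi <- cross(+1L)
  if (is.na(lo) || is.na(hi)) return(NA_real_)
  abs(hi - lo)
}
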