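#' Correction configuration
#'
#' Houses the constants of the amplitude-correction chain: per-metabolite
#' T1 (partial-saturation correction), flip angle and TR, deuterium
#' label-loss factors (default 1 = no correction), the natural-abundance
#' HDO concentration used by baseline quantification, and the nominal
#' concentrations of the two external reference phantoms.
#'
#' @param t1_s named per-metabolite T1 values in seconds.
#' @param flip_deg,tr_s acquisition constants (see [acq_params()]).
#' @param label_loss_factor named per-metabolite multiplicative factors.
#' @param natural_abundance_hdo_mm baseline HDO concentration in mM.
#' @param phantom_concentrations_mm low/high phantom concentrations in mM.
#' @return object of class `correction_config`.
#' @export
correction_config <- function(t1_s = c(water = 0.320, glucose = 0.064,
                                       glx = 0.146, lactate = 0.297),
                              flip_deg = 70, tr_s = 0.1558,
                              label_loss_factor = NULL,
                              natural_abundance_hdo_mm = 10.12,
                              phantom_concentrations_mm = c(6.4, 19.15)) {
  stopifnot(all(t1_s > 0), natural_abundance_hdo_mm > 0,
            length(phantom_concentrations_mm) == 2L,
            all(phantom_concentrations_mm > 0),
            phantom_concentrations_mm[1] != phantom_concentrations_mm[2])
  if (is.null(label_loss_factor)) {
    label_loss_factor <- stats::setNames(rep(1, length(t1_s)), names(t1_s))
  }
  stopifnot(all(label_loss_factor > 0))
  structure(list(t1_s = t1_s, flip_deg = flip_deg, tr_s = tr_s,
                 label_loss_factor = label_loss_factor,
                 natural_abundance_hdo_mm = natural_abundance_hdo_mm,
                 phantom_concentrations_mm = phantom_concentrations_mm),
            class = "correction_config")
}

#' Metabolite map container
#'
#' A 3D map of one metabolite with its units tag, the QC-retained voxel
#' mask and an append-only provenance chain of applied operations.
#'
#' @param values 3D numeric array.
#' @param metabolite metabolite name.
#' @param units units tag, e.g. `"au"` (arbitrary), `"mM"`, `"ratio"`.
#' @param mask logical 3D array of valid voxels.
#' @param provenance character vector of applied operations.
#' @return object of class `metabolite_map`.
#' @export
metabolite_map <- function(values, metabolite, units = "au", mask = NULL,
                           provenance = character()) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  stopifnot(all(dim(mask) == dim(values)))
  if (any(!is.finite(values[mask]))) {
    stop("map values must be finite on the mask")
  }
  structure(list(values = values, metabolite = metabolite, units = units,
                 mask = mask, provenance = provenance),
            class = "metabolite_map")
}

add_provenance <- function(map, step) {
  map$provenance <- c(map$provenance, step)
  map
}

#' Correct for partial radiofrequency saturation
#'
#' Divides the fitted amplitude by the steady-state saturation factor
#' `s = sin(a)(1 - E1)/(1 - cos(a) E1)`, `E1 = exp(-TR/T1)` (see
#' [saturation_factor()]), and by the label-loss factor.
#'
#' @param x a `metabolite_map` or a numeric amplitude (with `metabolite`
#'   given).
#' @param cfg a [correction_config()].
#' @param metabolite metabolite name; taken from the map when `x` is one.
#' @return the corrected map / amplitude.
#' @export
saturation_correct <- function(x, cfg = correction_config(),
                               metabolite = NULL) {
  if (inherits(x, "metabolite_map")) {
    met <- x$metabolite
    s <- saturation_factor(cfg$flip_deg, cfg$tr_s, cfg$t1_s[[met]])
    x$values <- x$values / (s * cfg$label_loss_factor[[met]])
    return(add_provenance(x, "saturation_correct"))
  }
  stopifnot(!is.null(metabolite))
  s <- saturation_factor(cfg$flip_deg, cfg$tr_s, cfg$t1_s[[metabolite]])
  x / (s * cfg$label_loss_factor[[metabolite]])
}

#' Gaussian point-spread function
#'
#' @param sigma_vox standard deviation in voxels (scalar or length 3).
#' @param size odd kernel size per axis.
#' @return 3D array normalised to unit sum.
#' @export
psf_gaussian <- function(sigma_vox = 0.6, size = 5L) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  size <- rep(as.integer(size), length.out = 3)
  stopifnot(all(size %% 2L == 1L), all(sigma_vox > 0))
  ax <- lapply(1:3, function(a) {
    x <- seq(-(size[a] %/% 2), size[a] %/% 2)
    exp(-x^2 / (2 * sigma_vox[a]^2))
  })
  k <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  k / sum(k)
}

#' Spatial response kernel of a Fourier CSI acquisition
#'
#' The point response of an `m`-sample Fourier encoding is the periodic
#' sinc (Dirichlet) kernel. Sampled exactly on the voxel grid it is a
#' delta; here it is integrated over voxel-sized cells (sub-voxel
#' averaging) so that a usable non-negative kernel of odd `size` results,
#' truncated and clipped at zero, normalised to unit sum. Intended as the
#' deconvolution kernel for [partial_volume_correct()].
#'
#' @param m number of phase-encoding samples per axis (scalar or length 3).
#' @param size odd kernel size per axis (default 5, i.e. 2 cycles).
#' @param oversample sub-voxel integration factor.
#' @return 3D array normalised to unit sum.
#' @export
psf_csi <- function(m = 10L, size = 5L, oversample = 9L) {
  m <- rep(as.integer(m), length.out = 3)
  size <- rep(as.integer(size), length.out = 3)
  stopifnot(all(size %% 2L == 1L), all(m >= 2L))
  dirichlet <- function(x, mm) {
    out <- sin(pi * x) / (mm * sin(pi * x / mm))
    out[abs(x) < 1e-12] <- 1
    out
  }
  ax <- lapply(1:3, function(a) {
    half <- size[a] %/% 2
    centers <- seq(-half, half)
    sub <- seq(-0.5, 0.5, length.out = oversample + 2L)[-c(1, oversample + 2L)]
    vapply(centers, function(cc) mean(dirichlet(cc + sub, m[a])), numeric(1))
  })
  k <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  k <- pmax(k, 0)
  k / sum(k)
}

# circular convolution of a 3D array with a small centered kernel via FFT
conv3_circ <- function(vol, kernel) {
  dims <- dim(vol)
  kd <- dim(kernel)
  big <- array(0, dims)
  idx <- lapply(1:3, function(a) {
    off <- seq_len(kd[a]) - (kd[a] %/% 2 + 1L)
    ((off) %% dims[a]) + 1L
  })
  big[idx[[1]], idx[[2]], idx[[3]]] <- kernel
  Re(stats::fft(stats::fft(vol) * stats::fft(big), inverse = TRUE)) /
    prod(dims)
}

#' Richardson-Lucy partial-volume correction
#'
#' Standard multiplicative Richardson-Lucy deconvolution of a non-negative
#' map by a non-negative unit-sum point-spread function: iterates
#' `u <- u * (K^T * (v / (K * u)))`. Non-negativity and total intensity are
#' preserved. Convolutions are circular; values outside the mask are
#' treated as zero.
#'
#' @param map a `metabolite_map` (non-negative on its mask) or 3D array.
#' @param psf point-spread function array with unit sum.
#' @param n_iter number of iterations.
#' @return the deconvolved map (same class as input).
#' @export
partial_volume_correct <- function(map, psf = psf_gaussian(), n_iter = 10L) {
  if (abs(sum(psf)) < 1e-12) stop("psf has zero sum")
  psf <- psf / sum(psf)
  is_map <- inherits(map, "metabolite_map")
  vol <- if (is_map) map$values else map
  vol[!is.finite(vol)] <- 0
  if (is_map) vol[!map$mask] <- 0
  # forgive round-off-scale negatives (e.g. from an FFT-based forward blur)
  tiny <- -1e-9 * max(abs(vol))
  vol[vol < 0 & vol >= tiny] <- 0
  if (any(vol < 0)) stop("map must be non-negative")
  psf_t <- psf[rev(seq_len(dim(psf)[1])), rev(seq_len(dim(psf)[2])),
               rev(seq_len(dim(psf)[3])), drop = FALSE]
  u <- vol
  eps <- .Machine$double.eps
  for (i in seq_len(n_iter)) {
    est <- conv3_circ(u, psf)
    ratio <- vol / pmax(est, eps)
    ratio[vol == 0] <- 0
    u <- u * conv3_circ(ratio, psf_t)
    u <- pmax(u, 0)
  }
  if (is_map) {
    out <- map
    out$values[map$mask] <- u[map$mask]
    add_provenance(out, sprintf("partial_volume_correct(n_iter=%d)", n_iter))
  } else {
    u
  }
}

#' Multiplicative bias-field correction
#'
#' Fits a smooth low-order polynomial in the voxel coordinates to the log
#' intensities inside the mask (the multiplicative intrinsic-component
#' model), divides the field out, and rescales so the mean intensity over
#' the mask is preserved exactly.
#'
#' @param map a `metabolite_map` (positive on its mask) or 3D array.
#' @param mask logical array; for a `metabolite_map` its own mask is used.
#' @param order polynomial order (default 2).
#' @return the corrected map (same class as input).
#' @export
bias_field_correct <- function(map, mask = NULL, order = 2L) {
  is_map <- inherits(map, "metabolite_map")
  vol <- if (is_map) map$values else map
  if (is.null(mask)) mask <- if (is_map) map$mask else array(TRUE, dim(vol))
  vals <- vol[mask]
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("map must be positive and finite on the mask")
  }
  co <- norm_coords(dim(vol))
  xg <- array(co$x, dim(vol))[mask]
  yg <- array(rep(co$y, each = dim(vol)[1]), dim(vol))[mask]
  zg <- array(rep(co$z, each = dim(vol)[1] * dim(vol)[2]), dim(vol))[mask]
  terms <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    terms[[length(terms) + 1L]] <- xg^i * yg^j * zg^k
  }
  X <- do.call(cbind, terms)
  if (sum(mask) < ncol(X) + 1L) {
    stop("mask too small to fit a polynomial bias field of order ", order)
  }
  beta <- stats::lm.fit(X, log(vals))$coefficients
  beta[is.na(beta)] <- 0
  field <- exp(as.vector(X %*% beta))
  corrected <- vals / field
  corrected <- corrected * mean(vals) / mean(corrected)
  if (is_map) {
    out <- map
    out$values[mask] <- corrected
    add_provenance(out, sprintf("bias_field_correct(order=%d)", order))
  } else {
    vol[mask] <- corrected
    vol
  }
}

# zero-pad the (fftshifted) spectrum of one axis, splitting the Nyquist bin
pad_axis_fft <- function(mat_f, n_old, n_new) {
  # mat_f: n_old x m matrix of unshifted FFT coefficients along axis 1
  m <- ncol(mat_f)
  out <- matrix(0 + 0i, n_new, m)
  h <- n_old %/% 2
  if (n_old %% 2L == 0L) {
    # positive freqs 0..h-1, nyquist h, negative h+1..n-1
    out[1:h, ] <- mat_f[1:h, , drop = FALSE]
    ny <- mat_f[h + 1L, , drop = FALSE]
    if (n_new > n_old) {
      out[h + 1L, ] <- ny / 2
      out[n_new - h + 1L, ] <- ny / 2
      if (h > 1) out[(n_new - h + 2L):n_new, ] <-
          mat_f[(h + 2L):n_old, , drop = FALSE]
    } else {
      out <- mat_f
    }
  } else {
    out[1:(h + 1L), ] <- mat_f[1:(h + 1L), , drop = FALSE]
    if (h > 0) out[(n_new - h + 1L):n_new, ] <-
        mat_f[(h + 2L):n_old, , drop = FALSE]
  }
  out
}

#' Fourier (zero-padded FFT) interpolation of a 3D map
#'
#' Upsamples a map to a finer grid by zero padding its spatial discrete
#' Fourier transform (Nyquist bins split symmetrically so real input stays
#' real). The mean value is preserved; a band-limited signal is
#' reproduced exactly at the new sample positions.
#'
#' @param map a `metabolite_map` or 3D array.
#' @param target_shape integer length-3, each `>=` the source shape.
#' @return interpolated array (or `metabolite_map` with an interpolated
#'   nearest-neighbour mask).
#' @export
fourier_interpolate <- function(map, target_shape) {
  is_map <- inherits(map, "metabolite_map")
  vol <- if (is_map) map$values else map
  src <- dim(vol)
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L)
  if (any(target_shape < src)) {
    stop("target shape must be >= source shape on every axis")
  }
  if (all(target_shape == src)) {
    return(map)
  }
  work <- vol
  work[!is.finite(work)] <- 0
  z <- work * (1 + 0i)
  for (axis in 1:3) {
    d <- dim(z)
    perm <- c(axis, setdiff(1:3, axis))
    zp <- aperm(z, perm)
    mat <- matrix(zp, d[axis], prod(d[-axis]))
    matf <- stats::mvfft(mat)
    padded <- pad_axis_fft(matf, d[axis], target_shape[axis])
    back <- stats::mvfft(padded, inverse = TRUE) / d[axis]
    newdim <- c(target_shape[axis], d[perm[2]], d[perm[3]])
    z <- aperm(array(back, newdim), order(perm))
  }
  out <- Re(z)
  if (is_map) {
    scale <- target_shape / src
    idx <- lapply(1:3, function(a)
      pmin(src[a], pmax(1L, ceiling((seq_len(target_shape[a]) - 0.5) /
                                      scale[a]))))
    newmask <- map$mask[idx[[1]], idx[[2]], idx[[3]]]
    res <- metabolite_map(out, map$metabolite, map$units, newmask,
                          map$provenance)
    add_provenance(res, sprintf("fourier_interpolate(%s)",
                                paste(target_shape, collapse = "x")))
  } else {
    out
  }
}

#' Quantify metabolite maps
#'
#' Converts fitted (corrected) amplitude maps to apparent concentrations
#' or normalised ratios:
#' \describe{
#'   \item{baseline}{voxel-wise ratio to the baseline water map times the
#'     natural-abundance HDO concentration; units mM.}
#'   \item{phantom}{two-point calibration line through the mean water
#'     signal of the low and high external phantoms; units mM. If the
#'     signal-axis intercept of the line exceeds 10% of the low phantom's
#'     signal a warning is issued.}
#'   \item{cerebellum}{ratio to the mean of the same metabolite over the
#'     cerebellum of the same exam; unitless.}
#' }
#' Quantifying an already quantified map is an error.
#'
#' @param map a `metabolite_map` in arbitrary units.
#' @param mode `"baseline"`, `"cerebellum"` or `"phantom"`.
#' @param atlas a `label_atlas`.
#' @param cfg a [correction_config()].
#' @param baseline_water baseline-exam water `metabolite_map` (required for
#'   `mode = "baseline"`).
#' @param water_map same-exam water `metabolite_map` including the phantom
#'   voxels (required for `mode = "phantom"`).
#' @return the quantified `metabolite_map`.
#' @export
quantify <- function(map, mode = c("baseline", "cerebellum", "phantom"),
                     atlas, cfg = correction_config(),
                     baseline_water = NULL, water_map = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "metabolite_map"))
  if (map$units != "au") {
    stop("map already quantified (units '", map$units, "')")
  }
  out <- map
  if (mode == "baseline") {
    if (is.null(baseline_water)) stop("baseline water map required")
    ref <- baseline_water$values
    valid <- map$mask & baseline_water$mask & is.finite(ref) & ref > 0
    if (!any(valid)) stop("no valid baseline water reference voxels")
    out$values[] <- NA_real_
    out$values[valid] <- map$values[valid] / ref[valid] *
      cfg$natural_abundance_hdo_mm
    out$mask <- valid
    out$units <- "mM"
  } else if (mode == "cerebellum") {
    cb <- atlas$labels == atlas$region_names[["cerebellum"]] & map$mask
    if (!any(cb)) stop("no QC-retained cerebellum voxels to normalise to")
    ref <- mean(map$values[cb])
    if (!is.finite(ref) || ref <= 0) stop("cerebellum reference mean <= 0")
    out$values <- map$values / ref
    out$units <- "ratio"
  } else {
    if (is.null(water_map)) stop("same-exam water map required")
    lo <- atlas$labels == atlas$region_names[["phantom_low"]]
    hi <- atlas$labels == atlas$region_names[["phantom_high"]]
    if (!any(lo) || !any(hi)) stop("both phantom regions are required")
    s_lo <- mean(water_map$values[lo])
    s_hi <- mean(water_map$values[hi])
    conc <- cfg$phantom_concentrations_mm
    slope <- (conc[2] - conc[1]) / (s_hi - s_lo)
    intercept <- conc[1] - slope * s_lo
    s0 <- -intercept / slope
    if (abs(s0) > 0.1 * abs(s_lo)) {
      warning("phantom calibration line intercept exceeds 10% of the low ",
              "phantom signal")
    }
    out$values <- slope * map$values + intercept
    out$units <- "mM"
  }
  add_provenance(out, sprintf("quantify(mode=%s)", mode))
}

#' Regional means of a map
#'
#' Arithmetic mean over QC-retained voxels per atlas region, plus the
#' derived `whole_brain` union of all brain regions. Regions with no
#' retained voxel are reported as `NA`, never as zero.
#'
#' @param map a `metabolite_map` or 3D array.
#' @param atlas a `label_atlas` congruent with the map.
#' @param mask optional logical array overriding the map's own mask.
#' @return data.frame with columns `region`, `mean`, `n_voxels`.
#' @export
regional_means <- function(map, atlas, mask = NULL) {
  vol <- if (inherits(map, "metabolite_map")) map$values else map
  if (is.null(mask)) {
    mask <- if (inherits(map, "metabolite_map")) map$mask
            else array(TRUE, dim(vol))
  }
  stopifnot(all(dim(vol) == dim(atlas$labels)))
  ids <- atlas$region_names
  brain_ids <- ids[!grepl("^phantom", names(ids))]
  region_names <- c("whole_brain", names(brain_ids))
  res <- lapply(region_names, function(nm) {
    sel <- if (nm == "whole_brain") atlas$labels %in% brain_ids
           else atlas$labels == ids[[nm]]
    sel <- sel & mask & is.finite(vol)
    n <- sum(sel)
    data.frame(region = nm,
               mean = if (n > 0) mean(vol[sel]) else NA_real_,
               n_voxels = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
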