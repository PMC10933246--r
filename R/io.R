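#' Write a spectral grid as a binary array with a JSON sidecar
#'
#' The complex FID array is stored as little-endian float64 pairs
#' (real, imaginary), voxel-major in array order; the sidecar (same path
#' with extension `.json`) records the dimensions, axes convention,
#' acquisition parameters and seed.
#'
#' @param grid a [spectral_grid()].
#' @param path output path for the binary payload (e.g. `exam.cfl`).
#' @return the path, invisibly.
#' @export
write_spectral_grid <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- as.vector(grid$data)
  inter <- as.vector(rbind(Re(vals), Im(vals)))
  writeBin(inter, con, size = 8L, endian = "little")
  meta <- list(
    dims = dim(grid$data),
    axes = c("x", "y", "z", "time"),
    layout = "interleaved re/im float64, little endian, column-major",
    bandwidth_hz = grid$acq$bandwidth_hz,
    n_spectral = grid$acq$n_spectral,
    larmor_mhz = grid$acq$larmor_mhz,
    water_ppm = grid$acq$water_ppm,
    flip_deg = grid$acq$flip_deg,
    tr_s = grid$acq$tr_s,
    fov_mm = grid$acq$fov_mm,
    seed = grid$seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spectral grid written by [write_spectral_grid()]
#'
#' @param path path to the binary payload.
#' @return a [spectral_grid()].
#' @export
read_spectral_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = 2L * n, size = 8L, endian = "little")
  vals <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  acq <- acq_params(matrix = dims[1:3], fov_mm = meta$fov_mm,
                    n_spectral = meta$n_spectral,
                    bandwidth_hz = meta$bandwidth_hz,
                    flip_deg = meta$flip_deg, tr_s = meta$tr_s,
                    larmor_mhz = meta$larmor_mhz, water_ppm = meta$water_ppm)
  spectral_grid(array(vals, dims), acq,
                seed = if (is.null(meta$seed)) NULL else meta$seed)
}

#' Export a spectrum as a CSV table
#'
#' @param spectrum a `dmi_spectrum`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(freq_hz = spectrum$freq_hz,
                              ppm = spectrum$ppm,
                              real = Re(spectrum$values),
                              imag = Im(spectrum$values),
                              magnitude = Mod(spectrum$values)),
                   path, row.names = FALSE)
  invisible(path)
}
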