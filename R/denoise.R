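#' Patch configuration for PCA denoising
#'
#' @param patch_shape integer length-3 spatial sliding-window size.
#' @param stride integer length-3 window stride (>= 1 per axis).
#' @return object of class `patch_config`.
#' @export
patch_config <- function(patch_shape = c(3L, 3L, 3L), stride = c(1L, 1L, 1L)) {
  patch_shape <- as.integer(patch_shape)
  stride <- as.integer(stride)
  stopifnot(length(patch_shape) == 3L, length(stride) == 3L,
            prod(patch_shape) >= 2L, all(stride >= 1L))
  structure(list(patch_shape = patch_shape, stride = stride),
            class = "patch_config")
}

# Marchenko-Pastur rank selection on eigenvalues of X X^H / n_large,
# lambda sorted descending, m = length(lambda) = small dimension.
# Returns smallest retained rank p such that the discarded eigenvalue
# spread is within the MP bulk width implied by its own mean.
mp_select_eig <- function(lambda, m, n_large) {
  for (p in 0:(m - 1L)) {
    tail_vals <- lambda[(p + 1L):m]
    sigma2 <- mean(tail_vals)
    gamma <- (m - p) / n_large
    # a numerically void tail (exact low rank) is trivially noise-consistent
    if (tail_vals[1] <= 1e-12 * lambda[1] ||
        (tail_vals[1] - tail_vals[m - p]) <= 4 * sqrt(gamma) * sigma2) {
      return(list(rank = p, noise_variance = sigma2))
    }
  }
  list(rank = m - 1L, noise_variance = lambda[m])
}

#' Automatic rank selection by the Marchenko-Pastur law
#'
#' Given the singular values of an `n_rows x n_cols` (Casorati) matrix,
#' returns the smallest retained rank such that the discarded eigenvalue
#' spectrum is consistent with the Marchenko-Pastur distribution of an
#' i.i.d. noise matrix of that shape, together with the implied per-entry
#' noise variance (mean of the discarded eigenvalues of `X X^H / n`, i.e.
#' the expectation of `|entry|^2` for pure noise).
#'
#' @param singular_values non-negative, sorted descending.
#' @param n_rows,n_cols matrix dimensions.
#' @return list with `rank` and `noise_variance`.
#' @export
mp_rank_select <- function(singular_values, n_rows, n_cols) {
  if (length(singular_values) < 2L) {
    stop("at least 2 singular values are required")
  }
  if (any(singular_values < 0) || is.unsorted(rev(singular_values))) {
    stop("singular values must be non-negative and sorted descending")
  }
  m <- min(n_rows, n_cols)
  n <- max(n_rows, n_cols)
  stopifnot(length(singular_values) == m)
  mp_select_eig(singular_values^2 / n, m, n)
}

#' Marchenko-Pastur PCA denoising of a CSI grid
#'
#' Slides a spatial window over the grid, forms the Casorati matrix of each
#' patch (rows = patch voxels, columns = spectral points), truncates it at
#' the Marchenko-Pastur rank (complex eigendecomposition of the spatial
#' Gram matrix) and averages the overlapping estimates uniformly. The
#' output grid has the shape of the input; the per-patch selected ranks and
#' noise-variance estimates are attached as attributes `mp_rank` and
#' `mp_noise_variance` (arrays over patch origins).
#'
#' @param grid a [spectral_grid()].
#' @param cfg a [patch_config()].
#' @return a denoised [spectral_grid()].
#' @export
denoise_grid <- function(grid, cfg = patch_config()) {
  dims <- dim(grid$data)[1:3]
  nt <- dim(grid$data)[4]
  ps <- cfg$patch_shape
  if (any(ps > dims)) stop("patch larger than grid")
  starts <- lapply(1:3, function(a) {
    s <- seq(1L, dims[a] - ps[a] + 1L, by = cfg$stride[a])
    # make sure the final voxels are covered even with stride > 1
    if (s[length(s)] != dims[a] - ps[a] + 1L) s <- c(s, dims[a] - ps[a] + 1L)
    s
  })
  m <- prod(ps)
  fids <- matrix(grid$data, prod(dims), nt)
  acc <- matrix(0 + 0i, prod(dims), nt)
  cnt <- numeric(prod(dims))
  rank_map <- array(NA_integer_, vapply(starts, length, integer(1)))
  nv_map <- array(NA_real_, dim(rank_map))
  lin <- array(seq_len(prod(dims)), dims)
  for (ia in seq_along(starts[[1]])) for (ib in seq_along(starts[[2]]))
    for (ic in seq_along(starts[[3]])) {
      ix <- starts[[1]][ia]; iy <- starts[[2]][ib]; iz <- starts[[3]][ic]
      vox <- as.vector(lin[ix:(ix + ps[1] - 1L), iy:(iy + ps[2] - 1L),
                           iz:(iz + ps[3] - 1L)])
      x <- fids[vox, , drop = FALSE]
      gram <- (x %*% Conj(t(x))) / nt
      eg <- eigen(gram, symmetric = TRUE)
      lambda <- pmax(Re(eg$values), 0)
      sel <- mp_select_eig(lambda, m, nt)
      r <- sel$rank
      xhat <- if (r == 0L) {
        matrix(0 + 0i, m, nt)
      } else {
        u <- eg$vectors[, seq_len(r), drop = FALSE]
        u %*% (Conj(t(u)) %*% x)
      }
      acc[vox, ] <- acc[vox, ] + xhat
      cnt[vox] <- cnt[vox] + 1
      rank_map[ia, ib, ic] <- r
      nv_map[ia, ib, ic] <- sel$noise_variance
    }
  out <- acc / cnt
  res <- spectral_grid(array(out, c(dims, nt)), grid$acq, seed = grid$seed)
  attr(res, "mp_rank") <- rank_map
  attr(res, "mp_noise_variance") <- nv_map
  res
}
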