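acq <- acq_params()
pri <- resonance_priors(acq)
t_ax <- time_axis(acq)

test_that("a noiseless FID at the prior initial values is recovered exactly", {
  a <- 5.3
  fid <- fid_model(a, 0, pi * 10, 0, t_ax)
  fv <- fit_voxel(fid, pri[pri$name == "water", ], acq)
  expect_true(fv$converged)
  expect_equal(fv$resonances$amplitude, a, tolerance = 1e-6)
  expect_equal(fv$resonances$frequency_hz, 0, tolerance = 1e-6)
  expect_equal(fv$resonances$lw_hz, 10, tolerance = 1e-6)
})

test_that("noiseless four-peak FIDs with perturbed parameters are refit to 1e-4", {
  cases <- list(
    list(a = c(6.4, 2.5, 2.2, 0.9), df = c(1.5, -2, 1, 2.5),
         lw_scale = c(1.1, 0.9, 1.05, 0.95), phase = 0.3),
    list(a = c(10, 1, 3, 2), df = c(-3, 3, -1, 0),
         lw_scale = c(0.8, 1.2, 1.0, 1.1), phase = -0.8)
  )
  for (cs in cases) {
    fid <- fid_model(cs$a, pri$freq_hz + cs$df,
                     pi * pri$lw_init_hz * cs$lw_scale,
                     rep(cs$phase, 4), t_ax)
    fv <- fit_voxel(fid, pri, acq)
    expect_true(fv$converged)
    expect_lt(max(abs(fv$resonances$amplitude - cs$a) / cs$a), 1e-4)
    expect_lt(max(abs(fv$resonances$frequency_hz -
                        (pri$freq_hz + cs$df))), 1e-3)
    expect_equal(fv$phase_rad, cs$phase, tolerance = 1e-4)
  }
})

test_that("the fit is invariant to a global FID scale", {
  set.seed(21)
  fid <- fid_model(c(6, 2.5, 2.2, 0.9), pri$freq_hz, pi * pri$lw_init_hz,
                   rep(0, 4), t_ax) +
    complex(real = rnorm(700, sd = 1), imaginary = rnorm(700, sd = 1))
  f1 <- fit_voxel(fid, pri, acq)
  f2 <- fit_voxel(100 * fid, pri, acq)
  expect_equal(f2$resonances$amplitude / f1$resonances$amplitude,
               rep(100, 4), tolerance = 1e-4)
  expect_equal(f2$resonances$frequency_hz, f1$resonances$frequency_hz,
               tolerance = 1e-4)
  expect_equal(f2$resonances$lw_hz, f1$resonances$lw_hz, tolerance = 1e-4)
  # CRLB% uses the (scaled) tail noise estimate, so percentages agree
  expect_equal(f2$resonances$crlb_percent, f1$resonances$crlb_percent,
               tolerance = 1e-3)
})

test_that("the residual never exceeds the starting residual", {
  set.seed(31)
  for (i in 1:5) {
    fid <- fid_model(runif(4, 0.5, 8), pri$freq_hz + runif(4, -3, 3),
                     pi * pri$lw_init_hz, rep(0, 4), t_ax) +
      complex(real = rnorm(700, sd = 2), imaginary = rnorm(700, sd = 2))
    fv <- fit_voxel(fid, pri, acq)
    expect_lte(fv$residual, fv$initial_residual)
  }
})

test_that("CRLB% scales linearly with the noise level", {
  fid <- fid_model(c(6, 2.5, 2.2, 0.9), pri$freq_hz, pi * pri$lw_init_hz,
                   rep(0, 4), t_ax)
  fv <- fit_voxel(fid, pri, acq)
  c1 <- crlb_percent(fv, 1)
  c2 <- crlb_percent(fv, 2)
  expect_equal(c2, 2 * c1, tolerance = 1e-10)
})

test_that("overlap raises the CRLB and separation restores the single-peak bound", {
  two <- function(sep_hz) {
    p <- resonance_priors(acq, ppm = c(4.8, 4.8 - sep_hz / acq$larmor_mhz),
                          names = c("a", "b"), lw_init_hz = c(10, 10),
                          t1_s = c(0.3, 0.3))
    fid <- fid_model(c(3, 3), p$freq_hz, pi * c(10, 10), c(0, 0), t_ax)
    crlb_percent(fit_voxel(fid, p, acq), 1)[["a"]]
  }
  single <- {
    p <- pri[pri$name == "water", ]
    fid <- fid_model(3, 0, pi * 10, 0, t_ax)
    crlb_percent(fit_voxel(fid, p, acq), 1)[["water"]]
  }
  near <- two(12)
  far <- two(300)
  expect_gt(near, far)
  expect_gt(near, single)
  expect_equal(far, single, tolerance = 0.05)
})

test_that("an all-zero FID is flagged, not an error", {
  fv <- fit_voxel(complex(real = rep(0, 700)), pri, acq)
  expect_false(fv$converged)
  rule <- qc_rule()
  expect_true(all(!is.finite(fv$resonances$crlb_percent) |
                    fv$resonances$crlb_percent == Inf))
})

test_that("QC excludes exactly the voxels violating the SNR or linewidth gates", {
  fixture <- data.frame(
    water_snr = c(4.9, 5.1, 5.1, 4.9, 20, 20, 5.1, 4.9, 100, 5.0),
    water_fwhm_hz = c(29, 29, 31, 31, 29, 31, 30, 30, 10, 29)
  )
  res <- qc_mask(fixture, qc_rule())
  expect_identical(res$retained,
                   c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
                     TRUE, FALSE))
  expect_identical(res$n_excluded, 6L)
  # a vacuous rule retains everything
  all_in <- qc_mask(fixture, qc_rule(water_snr_min = 0,
                                     water_linewidth_max_hz = Inf))
  expect_identical(all_in$n_excluded, 0L)
})

test_that("grid fits expose maps and tidy tables", {
  ex <- make_exam(acq = small_acq(), seed = 12)
  bm <- brain_mask(ex$atlas)
  fit <- fit_grid(ex$grid, ex$priors, mask = bm)
  amp <- fit_map(fit, "water")
  expect_equal(dim(amp), dim(ex$atlas$labels))
  expect_true(all(is.na(amp[!bm])))
  expect_true(all(amp[bm] >= 0))
  df <- as.data.frame(fit)
  expect_equal(nrow(df), sum(bm) * 4)
  expect_true(all(c("voxel", "resonance", "amplitude", "crlb_percent")
                  %in% names(df)))
})
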