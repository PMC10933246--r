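test_that("saturation factor matches its closed form and limits", {
  # fully relaxed 90-degree pulse: no correction
  expect_equal(saturation_factor(90, 100, 0.3), 1, tolerance = 1e-10)
  # hand-evaluated steady state at the acquisition constants
  a <- 70 * pi / 180
  e1 <- exp(-0.1558 / 0.320)
  expect_equal(saturation_factor(70, 0.1558, 0.320),
               sin(a) * (1 - e1) / (1 - cos(a) * e1), tolerance = 1e-12)
  # T1 -> 0 limit is sin(alpha)
  expect_equal(saturation_factor(70, 0.1558, 1e-9), sin(a),
               tolerance = 1e-6)
  expect_error(saturation_factor(0, 0.1558, 0.3))
})

test_that("saturation correction divides by the steady-state factor", {
  cfg <- correction_config()
  m <- metabolite_map(array(1, c(4, 4, 4)), "glucose")
  out <- saturation_correct(m, cfg)
  s <- saturation_factor(70, 0.1558, 0.064)
  expect_equal(out$values[1], 1 / s, tolerance = 1e-12)
  expect_match(out$provenance[length(out$provenance)], "saturation")
  expect_equal(saturation_correct(2, cfg, metabolite = "water"),
               2 / saturation_factor(70, 0.1558, 0.320))
})

test_that("Richardson-Lucy with a delta kernel is the identity", {
  set.seed(2)
  vol <- array(runif(6^3), c(6, 6, 6))
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  out <- partial_volume_correct(vol, delta, n_iter = 5)
  expect_equal(out, vol, tolerance = 1e-10)
  expect_error(partial_volume_correct(vol, array(0, c(3, 3, 3))),
               "zero sum")
})

test_that("Richardson-Lucy conserves flux and restores a blurred point source", {
  psf <- psf_gaussian(0.8, 5)
  truth <- array(0, c(12, 12, 12)); truth[6, 6, 6] <- 100
  blurred <- dmirep:::conv3_circ(truth, psf)
  expect_lte(max(blurred), 0.5 * max(truth))
  rec <- partial_volume_correct(blurred, psf, n_iter = 20)
  expect_gte(max(rec), 0.8 * max(truth))
  expect_equal(sum(rec), sum(blurred), tolerance = 1e-6)
  expect_true(all(rec >= 0))
})

test_that("the CSI point-spread kernel is a valid deconvolution kernel", {
  k <- psf_csi(10, 5)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_true(all(k >= 0))
  expect_equal(which.max(k), (length(k) + 1) %/% 2)  # centered
})

test_that("bias-field correction flattens a smooth gradient and preserves the mean", {
  set.seed(4)
  dims <- c(10, 10, 10)
  atl <- make_atlas(dims)
  mask <- brain_mask(atl)
  truth <- array(5, dims)
  co <- dmirep:::norm_coords(dims)
  grad <- 1 + 0.2 * array(co$x, dims)      # 20% linear shading
  biased <- truth * grad
  corrected <- bias_field_correct(biased, mask = mask, order = 2)
  cov_before <- sd(biased[mask] / truth[mask]) / mean(biased[mask] / truth[mask])
  cov_after <- sd(corrected[mask] / truth[mask]) /
    mean(corrected[mask] / truth[mask])
  expect_lt(cov_after, 0.5 * cov_before)
  expect_equal(mean(corrected[mask]), mean(biased[mask]), tolerance = 1e-10)
  # a flat map is untouched
  flat <- array(3, dims)
  expect_equal(bias_field_correct(flat, mask = mask), flat,
               tolerance = 1e-8)
})

test_that("Fourier interpolation is exact for constants and band-limited signals", {
  vol <- array(2.5, c(6, 6, 6))
  up <- fourier_interpolate(vol, c(12, 12, 12))
  expect_equal(up, array(2.5, c(12, 12, 12)), tolerance = 1e-10)
  expect_identical(fourier_interpolate(vol, c(6, 6, 6)), vol)
  expect_error(fourier_interpolate(vol, c(4, 6, 6)), "target shape")
  # single-frequency sinusoid: values at the new grid match the closed form
  n <- 8; m <- 16
  x <- (0:(n - 1))
  sine <- array(cos(2 * pi * 2 * x / n), c(n, 1, 1))
  vol3 <- array(rep(sine, times = 4), c(n, 2, 2))
  up3 <- fourier_interpolate(vol3, c(m, 2, 2))
  xs <- (0:(m - 1)) * n / m
  expect_equal(up3[, 1, 1], cos(2 * pi * 2 * xs / n), tolerance = 1e-6)
  # mean preserved
  expect_equal(mean(up3), mean(vol3), tolerance = 1e-10)
})

test_that("quantification modes anchor to their references", {
  atl <- make_atlas(c(6, 6, 6))
  dims <- dim(atl$labels)
  cfg <- correction_config()
  sig <- array(3, dims)
  m <- metabolite_map(sig, "glucose")

  # cerebellum mode: the cerebellum regional mean of the output is exactly 1
  set.seed(9)
  vals <- array(runif(prod(dims), 1, 4), dims)
  mm <- metabolite_map(vals, "glx")
  q <- quantify(mm, "cerebellum", atl, cfg)
  rm_ <- regional_means(q, atl)
  expect_equal(rm_$mean[rm_$region == "cerebellum"], 1, tolerance = 1e-12)
  expect_identical(q$units, "ratio")

  # phantom mode: a voxel at the low phantom's mean signal maps to 6.4 mM
  water <- array(0, dims)
  water[atl$labels == atlas_regions()[["phantom_low"]]] <- 2
  water[atl$labels == atlas_regions()[["phantom_high"]]] <- 6
  wm <- metabolite_map(water, "water")
  probe <- metabolite_map(array(2, dims), "glucose")
  qp <- quantify(probe, "phantom", atl, cfg, water_map = wm)
  expect_equal(qp$values[1], 6.4, tolerance = 1e-10)
  expect_identical(qp$units, "mM")

  # baseline mode: known concentration is recovered from the water ratio
  base_w <- metabolite_map(array(10.12, dims), "water")
  met <- metabolite_map(array(3.3, dims), "glucose")
  qb <- quantify(met, "baseline", atl, cfg, baseline_water = base_w)
  expect_equal(qb$values[qb$mask][1], 3.3, tolerance = 1e-10)

  # re-quantification is rejected
  expect_error(quantify(qb, "baseline", atl, cfg, baseline_water = base_w),
               "already quantified")
})

test_that("phantom calibration warns when the line misses the origin", {
  atl <- make_atlas(c(6, 6, 6))
  dims <- dim(atl$labels)
  water <- array(0, dims)
  water[atl$labels == atlas_regions()[["phantom_low"]]] <- 5
  water[atl$labels == atlas_regions()[["phantom_high"]]] <- 6
  wm <- metabolite_map(water, "water")
  probe <- metabolite_map(array(2, dims), "glucose")
  expect_warning(quantify(probe, "phantom", atl, correction_config(),
                          water_map = wm), "intercept")
})

test_that("baseline quantification round-trips noiseless synthetic data", {
  ex <- make_exam(acq = small_acq(), noiseless = TRUE)
  base <- make_exam(acq = small_acq(), timepoint = 0, noiseless = TRUE)
  # fit both exams, saturation-correct, take the ratio
  bm <- brain_mask(ex$atlas)
  cfg <- correction_config()
  f1 <- fit_grid(ex$grid, ex$priors, mask = bm)
  f0 <- fit_grid(base$grid, ex$priors[ex$priors$name == "water", ],
                 mask = bm)
  glc <- metabolite_map(ifelse(is.na(fit_map(f1, "glucose")), 0,
                               fit_map(f1, "glucose")), "glucose",
                        mask = bm)
  wat <- metabolite_map(ifelse(is.na(fit_map(f0, "water")), 0,
                               fit_map(f0, "water")), "water", mask = bm)
  glc <- saturation_correct(glc, cfg)
  wat <- saturation_correct(wat, cfg)
  q <- quantify(glc, "baseline", ex$atlas, cfg, baseline_water = wat)
  rm_ <- regional_means(q, ex$atlas)
  truth_frontal <- ex$truth$conc_mm[ex$truth$metabolite == "glucose" &
                                      ex$truth$region == "frontal"]
  got <- rm_$mean[rm_$region == "frontal"]
  expect_lt(abs(got - truth_frontal) / truth_frontal, 0.05)
})

test_that("regional means honor the QC mask and report missing regions as NA", {
  atl <- make_atlas(c(6, 6, 6))
  dims <- dim(atl$labels)
  vol <- array(7, dims)
  expect_true(all(abs(regional_means(vol, atl)$mean - 7) < 1e-12))

  # hand-built three-voxel region: values 1, 2, 3 -> mean 2
  vox <- which(atl$labels == atlas_regions()[["frontal"]])[1:3]
  vol2 <- array(NA_real_, dims)
  mask <- array(FALSE, dims)
  vol2[vox] <- c(1, 2, 3); mask[vox] <- TRUE
  rm2 <- regional_means(vol2, atl, mask = mask)
  expect_equal(rm2$mean[rm2$region == "frontal"], 2)
  expect_equal(rm2$n_voxels[rm2$region == "frontal"], 3L)
  # regions with no retained voxels come back missing, never zero
  expect_true(is.na(rm2$mean[rm2$region == "cerebellum"]))

  # half-masked region equals brute-force recomputation
  set.seed(14)
  vol3 <- array(runif(prod(dims)), dims)
  fr <- which(atl$labels == atlas_regions()[["frontal"]])
  mask3 <- array(FALSE, dims); mask3[fr[seq(1, length(fr), by = 2)]] <- TRUE
  rm3 <- regional_means(vol3, atl, mask = mask3)
  expect_equal(rm3$mean[rm3$region == "frontal"],
               mean(vol3[fr[seq(1, length(fr), by = 2)]]))
})
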