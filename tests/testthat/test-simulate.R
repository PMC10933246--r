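test_that("zero variance gives identical truth curves across subjects and sessions", {
  atl <- make_atlas(c(6, 6, 6))
  des <- study_design(3, 2, c(0, 30, 75, 120), seed = 4)
  vp <- variance_params(between_subject_cov = 0, within_subject_cov = 0)
  tr <- sample_truth(des, atl, vp)
  spread <- aggregate(conc_mm ~ timepoint_min + region + metabolite,
                      tr, function(x) diff(range(x)))
  expect_true(all(spread$conc_mm == 0))
})

test_that("truth respects the baseline invariants", {
  atl <- make_atlas(c(6, 6, 6))
  tr <- sample_truth(study_design(2, 2, c(0, 120), seed = 1), atl,
                     variance_params())
  base <- tr[tr$timepoint_min == 0, ]
  expect_true(all(base$conc_mm[base$metabolite != "water"] == 0))
  expect_true(all(base$conc_mm[base$metabolite == "water"] == 10.12))
})

test_that("truth tables are reproducible from the seed", {
  atl <- make_atlas(c(6, 6, 6))
  des <- study_design(4, 2, c(0, 120), seed = 77)
  vp <- variance_params()
  expect_identical(sample_truth(des, atl, vp), sample_truth(des, atl, vp))
})

test_that("empirical between-subject CoV converges to the configured value", {
  atl <- make_atlas(c(6, 6, 6))
  des <- study_design(2000, 1, c(0, 120), seed = 5)
  vp <- variance_params(between_subject_cov = 0.20, within_subject_cov = 0)
  tr <- sample_truth(des, atl, vp)
  glx <- tr[tr$metabolite == "glx" & tr$timepoint_min == 120 &
              tr$region == "frontal", ]
  cov_emp <- sd(glx$conc_mm) / mean(glx$conc_mm)
  expect_gt(cov_emp, 0.19)
  expect_lt(cov_emp, 0.21)
})

test_that("a noiseless water-only voxel starts at the summed amplitude", {
  acq <- small_acq()
  pri <- resonance_priors(acq)
  atl <- make_atlas(acq$matrix)
  vp <- variance_params(0, 0, noise_sd = 0)
  tr <- sample_truth(study_design(1, 1, c(0, 120), seed = 1), atl, vp)
  te <- tr[tr$timepoint_min == 0, ]  # water only at baseline
  g <- synthesize_csi(te, atl, acq, vp, pri, beta = 0)
  vox <- which(atl$labels == atlas_regions()[["thalamus"]])[1]
  idx <- arrayInd(vox, dim(atl$labels))
  fid <- g$data[idx[1], idx[2], idx[3], ]
  sat <- saturation_factor(acq$flip_deg, acq$tr_s, pri$t1_s)
  expect_equal(Re(fid[1]), 10.12 * sat[pri$name == "water"],
               tolerance = 1e-10)
  expect_equal(Im(fid[1]), 0, tolerance = 1e-10)
})

test_that("noiseless spectra are linear in concentration", {
  ex <- make_exam(noise_sd = 0)
  te2 <- ex$truth
  te2$conc_mm[te2$metabolite == "glucose"] <-
    2 * te2$conc_mm[te2$metabolite == "glucose"]
  g2 <- synthesize_csi(te2, ex$atlas, ex$acq, ex$vp, ex$priors, beta = 0)
  # difference grid contains exactly the extra glucose component
  diffg <- g2$data - ex$grid$data
  vox <- which(ex$atlas$labels == atlas_regions()[["frontal"]])[1]
  idx <- arrayInd(vox, dim(ex$atlas$labels))
  dfid <- diffg[idx[1], idx[2], idx[3], ]
  glc <- ex$truth[ex$truth$metabolite == "glucose" &
                    ex$truth$region == "frontal", "conc_mm"]
  sat <- saturation_factor(ex$acq$flip_deg, ex$acq$tr_s, ex$priors$t1_s)
  expect_equal(Re(dfid[1]), glc * sat[ex$priors$name == "glucose"],
               tolerance = 1e-8)
})

test_that("phantom voxels carry only water at nominal concentrations", {
  ex <- make_exam(noise_sd = 0)
  pri <- ex$priors
  sat_w <- saturation_factor(ex$acq$flip_deg, ex$acq$tr_s,
                             pri$t1_s[pri$name == "water"])
  for (ph in c("phantom_low", "phantom_high")) {
    vox <- which(ex$atlas$labels == atlas_regions()[[ph]])[1]
    idx <- arrayInd(vox, dim(ex$atlas$labels))
    fid <- ex$grid$data[idx[1], idx[2], idx[3], ]
    conc <- ex$vp$phantom_mm[[if (ph == "phantom_low") 1 else 2]]
    expect_equal(Re(fid[1]), conc * sat_w, tolerance = 1e-8)
  }
})

test_that("the B1 field spans +/-beta from center to corner", {
  b1 <- b1_field(c(10, 10, 10), 0.07)
  expect_lt(max(b1), 1.07 + 1e-9)
  expect_gt(max(b1), 1.06)          # near-center voxel
  expect_gt(min(b1), 1 - 0.07 - 1e-9)
  expect_lt(min(b1), 1 - 0.04)      # corner voxel center
})

test_that("identical seeds give bit-identical studies", {
  acq <- small_acq(n_spectral = 100L)
  des <- study_design(2, 2, c(0, 120), seed = 9)
  s1 <- simulate_study(des, acq = acq)
  s2 <- simulate_study(des, acq = acq)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$exams, s2$exams)
  expect_identical(s1$raw[[1]]$data, s2$raw[[1]]$data)
  expect_identical(s1$raw[[length(s1$raw)]]$data,
                   s2$raw[[length(s2$raw)]]$data)
})
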