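# shared fixtures: small acquisitions and single-exam synthetic grids

small_acq <- function(matrix = c(6L, 6L, 6L), n_spectral = 700L) {
  acq_params(matrix = matrix, n_spectral = n_spectral)
}

# one synthesized exam at a given timepoint with zero subject/session
# variance, returning everything needed to compare against ground truth
make_exam <- function(acq = small_acq(), timepoint = 120, seed = 11,
                      beta = 0, noise_sd = 2.7, noiseless = FALSE) {
  pri <- resonance_priors(acq)
  atl <- make_atlas(acq$matrix, fov_mm = acq$fov_mm)
  vp <- variance_params(between_subject_cov = 0, within_subject_cov = 0,
                        noise_sd = noise_sd)
  des <- study_design(1, 1, unique(c(0, timepoint)), seed = seed)
  truth <- sample_truth(des, atl, vp)
  te <- truth[truth$timepoint_min == timepoint, ]
  grid <- synthesize_csi(te, atl, acq, vp, pri, seed = seed, beta = beta,
                         noiseless = noiseless)
  list(grid = grid, truth = te, atlas = atl, acq = acq, priors = pri,
       vp = vp)
}
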