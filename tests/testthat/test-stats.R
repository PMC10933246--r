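test_that("between-subject CoV matches hand-computed values", {
  expect_equal(between_subject_cov(c(2, 4, 6)), 50)
  expect_equal(between_subject_cov(c(5, 5, 5)), 0)
  # scale invariance
  expect_equal(between_subject_cov(c(2, 4, 6) * 3.7),
               between_subject_cov(c(2, 4, 6)))
  # sessions are averaged per subject first
  m <- cbind(c(2, 4, 6), c(2, 4, 6))
  expect_equal(between_subject_cov(m), 50)
  expect_error(between_subject_cov(3), "at least 2")
  expect_error(between_subject_cov(c(-2, 2)), "positive")
})

test_that("within-subject CoV matches the paired-difference formula", {
  ri <- repeatability_input(c(10, 10), c(12, 8))
  expect_equal(within_subject_cov(ri), 20)
  expect_equal(within_subject_cov(repeatability_input(c(3, 5), c(3, 5))), 0)
  # symmetric in exam order and scale invariant
  expect_equal(within_subject_cov(repeatability_input(c(12, 8), c(10, 10))),
               20)
  expect_equal(within_subject_cov(repeatability_input(c(10, 10) * 7,
                                                      c(12, 8) * 7)), 20)
  # the two denominator conventions agree for complete pairs
  expect_equal(within_subject_cov(ri, denominator = "pair_means"), 20)
  expect_error(repeatability_input(1:3, 1:2), "matched")
})

test_that("the repeatability coefficient is exactly 1.96 sqrt(2) times wsCoV", {
  expect_equal(repeatability_coefficient(0), 0)
  expect_equal(repeatability_coefficient(10), 1.96 * sqrt(2) * 10)
  expect_error(repeatability_coefficient(-1), ">= 0")
})

test_that("printed whole-brain table rows are reproduced from their wsCoV", {
  rows <- list(c(5.4, 15.0), c(6.9, 19.1), c(15.7, 43.5), c(8.9, 24.7),
               c(8.5, 23.6))
  for (r in rows) {
    expect_lt(abs(repeatability_coefficient(r[1]) - r[2]), 0.15)
  }
})

test_that("Bland-Altman statistics follow their definitions", {
  same <- bland_altman(repeatability_input(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$bias, 0)
  expect_equal(same$lower_loa, 0)
  expect_equal(same$upper_loa, 0)
  off <- bland_altman(repeatability_input(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(off$bias, 1)
  expect_equal(off$lower_loa, 1)
  expect_equal(off$upper_loa, 1)
  # reversing the exams negates the bias and mirrors the limits
  set.seed(5)
  e1 <- rnorm(10, 10); e2 <- rnorm(10, 11)
  ba <- bland_altman(repeatability_input(e1, e2))
  rev <- bland_altman(repeatability_input(e2, e1))
  expect_equal(rev$bias, -ba$bias)
  expect_equal(rev$lower_loa, -ba$upper_loa)
  expect_equal(rev$upper_loa, -ba$lower_loa)
})

test_that("the quadratic dynamics fit equals the normal-equation solution", {
  t <- c(0, 30, 75, 120)
  y <- 1 + 2 * t - 0.01 * t^2
  cf <- dynamics_fit(t, y)
  expect_equal(unname(cf), c(1, 2, -0.01), tolerance = 1e-9)
  # constant data: zero linear and quadratic terms
  cf0 <- dynamics_fit(t, rep(4, 4))
  expect_equal(unname(cf0[2:3]), c(0, 0), tolerance = 1e-12)
  # noisy data against an independent closed-form OLS solve
  set.seed(8)
  tt <- rep(c(0, 30, 75, 120), each = 6)
  yy <- 2 + 0.05 * tt - 1e-4 * tt^2 + rnorm(length(tt), sd = 0.3)
  X <- cbind(1, tt, tt^2)
  beta <- solve(t(X) %*% X, t(X) %*% yy)
  expect_equal(unname(dynamics_fit(tt, yy)), as.numeric(beta),
               tolerance = 1e-9)
  expect_error(dynamics_fit(c(0, 0, 30), c(1, 2, 3)), "distinct")
})

test_that("repeatability tables satisfy the RC ratio invariant row by row", {
  set.seed(12)
  regional <- expand.grid(subject = 1:6, session = 1:2,
                          timepoint_min = c(30, 120),
                          region = c("whole_brain", "frontal"),
                          metabolite = c("glucose", "glx"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  regional$value <- exp(rnorm(nrow(regional), log(3), 0.15))
  tab <- repeatability_table(regional)
  expect_gt(nrow(tab), 0)
  expect_equal(tab$repeatability_coefficient_pct /
                 tab$within_subject_cov_pct,
               rep(1.96 * sqrt(2), nrow(tab)), tolerance = 1e-9)
  expect_true(all(tab$within_subject_cov_pct >= 0))
  expect_true(all(tab$n == 6))
  # a common rescaling of the data leaves every statistic unchanged
  regional2 <- regional
  regional2$value <- regional2$value * 42
  tab2 <- repeatability_table(regional2)
  expect_equal(tab2$within_subject_cov_pct, tab$within_subject_cov_pct)
  expect_equal(tab2$between_subject_cov_pct, tab$between_subject_cov_pct)
})
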