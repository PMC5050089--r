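test_that("biomarker-only estimator is the difference of sub-study means", {
  # per-individual replicate means {1,2,3} vs {2,3,4}
  d <- trial_dataset(rep(1:2, each = 3), q = c(1, 2, 3, 2, 3, 4),
                     m = cbind(c(1, 2, 3, 2, 3, 4), c(1, 2, 3, 2, 3, 4)))
  est <- estimate_theta_bio(d)
  expect_equal(est$estimate, 1.0)
  expect_equal(est$variance, 1 / 3 + 1 / 3)

  same <- trial_dataset(rep(1:2, each = 3), q = rep(2, 6),
                        m = cbind(rep(2, 6), rep(2, 6) + 1e-9))
  expect_equal(estimate_theta_bio(same)$estimate, 0, tolerance = 1e-12)
})

test_that("noise-free data recover the error-model coefficients exactly", {
  d <- noise_free_dataset(a0 = c(2, 1), a1 = c(0.5, 0.8))
  a <- estimate_alphas(d, "differential")
  expect_equal(a$alpha1, c(0.5, 0.8), tolerance = 1e-12)
  expect_equal(a$alpha0, c(2, 1), tolerance = 1e-12)
  expect_true(a$valid)

  shared <- noise_free_dataset(a0 = c(0.9, 0.9), a1 = c(0.65, 0.65))
  an <- estimate_alphas(shared, "nondifferential")
  expect_equal(an$alpha1, 0.65, tolerance = 1e-12)
  expect_equal(an$alpha0, 0.9, tolerance = 1e-12)
})

test_that("all MoM point estimates agree with the brute-force oracle", {
  for (seed in 1:5) {
    cfg <- scenario_config(if (seed %% 2) "differential" else
                             "nondifferential",
                           n_per_group = 60, calib_fraction = 0.5,
                           sigma2_Q = 0.3)
    d <- simulate_trial(cfg, seed = seed)
    for (err in c("differential", "nondifferential")) {
      o <- oracle_mom(d, err)
      f <- mom_fit(d, err)
      expect_equal(f$theta_bio, o$theta_bio, tolerance = 1e-10)
      expect_equal(f$theta_sr, o$theta_sr, tolerance = 1e-10)
      expect_equal(f$alpha0, o$alpha0, tolerance = 1e-10)
      expect_equal(f$alpha1, o$alpha1, tolerance = 1e-10)
      expect_equal(f$sigma2_M, o$sigma2_M, tolerance = 1e-10)
      expect_equal(f$sigma2_Q, o$sigma2_Q, tolerance = 1e-10)
      expect_equal(estimate_theta_bio(d)$variance, o$var_bio,
                   tolerance = 1e-10)
    }
  }
  # the toy fixture, checked on every quantity at tight tolerance
  d <- toy_dataset()
  for (err in c("differential", "nondifferential")) {
    o <- oracle_mom(d, err)
    f <- mom_fit(d, err)
    expect_equal(f$theta_sr, o$theta_sr, tolerance = 1e-12)
    expect_equal(f$alpha1, o$alpha1, tolerance = 1e-12)
  }
})

test_that("the self-report estimator follows the corrected-difference form", {
  # group means: Qbar1 = 4.0, Qbar1s = 4.1, Qbar2 = 5.0, Qbar2s = 4.8,
  # Mbar1 = 1.0, Mbar2 = 0.6; slopes set to (0.8, 0.5)
  d <- trial_dataset(
    group = rep(1:2, each = 4),
    q = c(4.0, 4.2, 3.9, 3.9, 4.7, 4.9, 5.35, 5.05),
    m = rbind(c(0.9, 1.1), c(1.1, 0.9), NA, NA,
              c(0.5, 0.7), c(0.7, 0.5), NA, NA))
  alphas <- structure(list(error = "differential", alpha0 = c(0, 0),
                           alpha1 = c(0.8, 0.5), valid = TRUE),
                      class = "mom_alphas")
  got <- estimate_theta_sr(d, alphas)
  expect_equal(got, (5.0 - 4.8) / 0.5 - (4.0 - 4.1) / 0.8 + (0.6 - 1.0))
  expect_equal(got, 0.125)

  # non-differential consistency at the true slope
  alphas_nd <- structure(list(error = "nondifferential", alpha0 = 0.9,
                              alpha1 = 0.65, valid = TRUE),
                         class = "mom_alphas")
  d2 <- trial_dataset(rep(1:2, each = 3),
                      q = c(4.0, 4.1, 4.2, 3.675, 3.775, 3.875),
                      m = cbind(rep(c(4.5, 4.0), each = 3),
                                rep(c(4.5, 4.0), each = 3)))
  expect_equal(estimate_theta_sr(d2, alphas_nd), -0.325 / 0.65)

  bad <- structure(list(error = "differential", alpha0 = c(0, 0),
                        alpha1 = c(0, 0.5), valid = FALSE),
                   class = "mom_alphas")
  expect_error(estimate_theta_sr(d, bad), "slope")
})

test_that("error-variance estimates vanish for replicates without error", {
  d <- noise_free_dataset()
  a <- estimate_alphas(d, "differential")
  ev <- estimate_error_variances(d, a)
  expect_equal(ev$sigma2_M, c(0, 0), tolerance = 1e-12)
  expect_equal(ev$sigma2_Q, c(0, 0), tolerance = 1e-12)
  expect_true(ev$valid)
})

test_that("inverse-variance combination uses the optimal-weight formulas", {
  # symmetric case
  c1 <- combine_estimates(0.2, 0.4, 1, 1, 0)
  expect_equal(c1$weight_bio, 0.5)
  expect_equal(c1$estimate, 0.3)
  expect_equal(c1$variance, 0.5)
  # worked closed-form case
  c2 <- combine_estimates(0, 1, var_bio = 1, var_sr = 2, cov_bio_sr = 0.5)
  expect_equal(c2$weight_bio, 0.75)
  expect_equal(c2$variance, (2 - 0.25) / 2)
  expect_equal(c2$estimate, 0.25)
  # a huge self-report variance pushes all weight onto the biomarkers
  c3 <- combine_estimates(0.2, 9, 1, 1e12, 0)
  expect_equal(c3$weight_bio, 1, tolerance = 1e-9)
  expect_equal(c3$estimate, 0.2, tolerance = 1e-6)
  # combined variance never exceeds either component when valid
  for (seed in 1:20) {
    set.seed(seed)
    vb <- runif(1, 0.5, 2); vs <- runif(1, 0.5, 2)
    cv <- runif(1, -0.5, 0.5) * sqrt(vb * vs)
    cc <- combine_estimates(0, 1, vb, vs, cv)
    expect_true(cc$valid)
    expect_lte(cc$variance, min(vb, vs) + 1e-12)
  }
  # non-positive-definite input is flagged
  expect_false(combine_estimates(0, 1, 1, 1, 1.5)$valid)
})

test_that("estimating-equation variance of the biomarker arm matches the
           closed-form sample-variance expression", {
  cfg <- scenario_config("differential", n_per_group = 80,
                         calib_fraction = 0.5, sigma2_Q = 0.3)
  d <- simulate_trial(cfg, seed = 4)
  f <- mom_fit(d, "differential")
  expect_equal(f$var_bio, estimate_theta_bio(d)$variance, tolerance = 1e-12)
})

test_that("full calibration makes the combined estimator the biomarker one", {
  cfg <- scenario_config("differential", n_per_group = 150,
                         calib_fraction = 1)
  d <- simulate_trial(cfg, seed = 8)
  f <- mom_fit(d, "differential")
  expect_equal(f$theta_sr, f$theta_bio, tolerance = 1e-12)
  expect_equal(f$theta_combined, f$theta_bio, tolerance = 1e-10)
  expect_equal(f$weight_bio, 1)
})

test_that("degenerate replicate covariance flags the fit invalid", {
  # anticorrelated replicates make cov(M1, M2) negative
  set.seed(2)
  n <- 40
  e <- rnorm(n)
  m1 <- 4 + e; m2 <- 4 - e + rnorm(n, 0, 0.01)
  d <- trial_dataset(rep(1:2, each = n / 2), q = rnorm(n, 4, 0.3),
                     m = cbind(m1, m2))
  f <- mom_fit(d, "differential")
  expect_false(f$valid)
  expect_match(f$invalid_reasons, "replicate covariance", all = FALSE)
})
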