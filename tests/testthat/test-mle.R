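test_that("implied moments follow the measurement-model structure", {
  mom <- implied_moments(muT = c(4.612, 4.123), sigma2_T = c(0.123, 0.205),
                         sigma2_M = c(0.205, 0.246),
                         sigma2_Q = c(0.300, 0.284),
                         alpha0 = c(0.287, 1.534), alpha1 = c(0.799, 0.494))
  g1 <- mom[[1]]
  expect_equal(g1$cov[1, 1], 0.123 + 0.205)
  expect_equal(g1$cov[1, 2], 0.123)
  expect_equal(g1$cov[1, 3], 0.799 * 0.123)
  expect_equal(g1$cov[3, 3], 0.799^2 * 0.123 + 0.300)
  expect_equal(g1$mean[3], 0.287 + 0.799 * 4.612)
  for (g in mom) {
    expect_identical(g$cov, t(g$cov))
    expect_true(all(eigen(g$cov, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-12))
  }
  # zero slope decouples the self-report from the biomarkers
  z <- implied_moments(4, 1, 0.2, 0.3, 0.5, c(0, 0))
  expect_equal(z[[1]]$cov[1:2, 3], c(0, 0))
  expect_error(implied_moments(4, -1, 0.2, 0.3, 0.5, 1), "non-negative")
})

test_that("noise-free data return the group sample means of true intake", {
  d <- noise_free_dataset(a0 = c(0.5, 0.2), a1 = c(0.9, 1.1),
                          t1 = c(3.8, 4.1, 4.6, 4.9, 5.1),
                          t2 = c(3.1, 3.6, 4.0, 4.4, 4.9))
  fit <- suppressWarnings(ml_fit(d, "differential", vcov = FALSE))
  expect_equal(unname(fit$params["muT1"]), mean(c(3.8, 4.1, 4.6, 4.9, 5.1)),
               tolerance = 1e-5)
  expect_equal(unname(fit$params["muT2"]), mean(c(3.1, 3.6, 4.0, 4.4, 4.9)),
               tolerance = 1e-5)
  expect_true(fit$boundary)
})

test_that("ML and MoM agree on a simulated dataset within sampling error", {
  cfg <- scenario_config("differential", sigma2_Q = 0.3,
                         calib_fraction = 0.5, n_per_group = 500)
  d <- simulate_trial(cfg, seed = 17)
  ml <- ml_fit(d, "differential")
  mm <- mom_fit(d, "differential")
  expect_true(ml$converged)
  expect_lt(abs(ml$effect - mm$theta_combined), 2 * mm$se_combined)
  # model-based SEs exist and are positive for every free parameter
  expect_true(all(diag(ml$vcov_model) > 0))
})

test_that("non-differential and equal-variance constraints tie parameters", {
  cfg <- scenario_config("nondifferential", sigma2_Q = 0.3,
                         calib_fraction = 0.5, n_per_group = 300)
  d <- simulate_trial(cfg, seed = 19)
  fit <- ml_fit(d, "nondifferential", equal_sigma_T = TRUE,
                equal_sigma_M = TRUE, equal_sigma_Q = TRUE)
  p <- fit$params
  expect_identical(unname(p["alpha0_1"]), unname(p["alpha0_2"]))
  expect_identical(unname(p["alpha1_1"]), unname(p["alpha1_2"]))
  expect_identical(unname(p["sigma2_T1"]), unname(p["sigma2_T2"]))
  expect_equal(fit$npar, 7)
  full <- ml_fit(d, "nondifferential")
  expect_equal(full$npar, 10)
})

test_that("log-likelihoods are monotone under nesting and the LRT behaves", {
  cfg <- scenario_config("nondifferential", sigma2_Q = 0.3,
                         calib_fraction = 0.5, n_per_group = 400)
  d <- simulate_trial(cfg, seed = 23)
  f_diff <- ml_fit(d, "differential")
  f_nd <- ml_fit(d, "nondifferential")
  f_nd_eq <- ml_fit(d, "nondifferential", equal_sigma_T = TRUE,
                    equal_sigma_M = TRUE, equal_sigma_Q = TRUE)
  expect_gte(f_diff$loglik, f_nd$loglik - 1e-6)
  expect_gte(f_nd$loglik, f_nd_eq$loglik - 1e-6)

  lt <- lrt(f_diff, f_nd)
  expect_equal(lt$df, 2)
  expect_gte(lt$statistic, 0)
  expect_true(lt$p_value >= 0 && lt$p_value <= 1)

  self <- lrt(f_diff, f_diff, df = 2)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  w <- wald_differential(f_diff)
  expect_equal(w$df, 2)
  expect_gte(w$statistic, 0)
})

test_that("sandwich variance tracks the model-based variance under the
           correct model", {
  cfg <- scenario_config("differential", sigma2_Q = 0.3,
                         calib_fraction = 0.5, n_per_group = 1500)
  d <- simulate_trial(cfg, seed = 29)
  fit <- ml_fit(d, "differential")
  sv <- sandwich_vcov(d, fit)
  expect_lt(abs(attr(sv, "effect_se") / fit$effect_se - 1), 0.15)
  ratios <- sqrt(diag(sv)) / sqrt(diag(fit$vcov_model))
  expect_true(all(abs(ratios - 1) < 0.30))
})

test_that("the differential-error test has near-nominal size under the null",
{
  # data generated non-differential: LRT at level 0.05 should reject ~5%
  n_rej <- 0
  n_rep <- 60
  set.seed(31)
  seeds <- sample.int(2^31 - 2, n_rep)
  for (s in seeds) {
    cfg <- scenario_config("nondifferential", sigma2_Q = 0.3,
                           calib_fraction = 0.5, n_per_group = 150)
    d <- simulate_trial(cfg, seed = s)
    f1 <- ml_fit(d, "differential", vcov = FALSE)
    f0 <- ml_fit(d, "nondifferential", vcov = FALSE)
    p <- lrt(f1, f0)$p_value
    n_rej <- n_rej + (p < 0.05)
  }
  # 3 binomial SDs around 0.05 at 60 replicates
  expect_lte(n_rej / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
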