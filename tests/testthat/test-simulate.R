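test_that("the generator reproduces the error-model structure exactly when
           noise-free", {
  cfg <- scenario_config("differential", sigma2_M = 0, sigma2_Q = 0,
                         n_per_group = 50, calib_fraction = 1)
  d <- simulate_trial(cfg, seed = 1)
  t_true <- attr(d, "t_true")
  expect_identical(d$m[, 1], t_true)
  expect_identical(d$m[, 2], t_true)
  a0 <- c(0.3, 1.5)[d$group]; a1 <- c(0.8, 0.5)[d$group]
  expect_equal(d$q, a0 + a1 * t_true, tolerance = 1e-12)
})

test_that("generated second moments match the model", {
  cfg <- scenario_config("differential", n_per_group = 100000,
                         calib_fraction = 1)
  d <- simulate_trial(cfg, seed = 2)
  for (i in 1:2) {
    gi <- d$group == i
    # var(Mk) = sigma2_T + sigma2_M = 0.3; cov(M1, M2) = sigma2_T = 0.1
    expect_equal(var(d$m[gi, 1]), 0.3, tolerance = 0.02)
    expect_equal(cov(d$m[gi, 1], d$m[gi, 2]), 0.1, tolerance = 0.05)
    # generator-to-estimator consistency: cov(Q, Mbar)/cov(M1,M2) -> alpha1
    mbar <- rowMeans(d$m[gi, ])
    a1 <- cov(d$q[gi], mbar) / cov(d$m[gi, 1], d$m[gi, 2])
    expect_equal(a1, c(0.8, 0.5)[i], tolerance = 0.03)
  }
  expect_equal(attr(d, "true_effect"), -0.5)
})

test_that("masking is stratified, sized by round(fraction * n), and exactly
           reproducible", {
  cfg <- scenario_config("differential", n_per_group = 500,
                         calib_fraction = 0.10)
  d1 <- simulate_trial(cfg, seed = 5)
  d2 <- simulate_trial(cfg, seed = 5)
  expect_identical(d1$q, d2$q)
  expect_identical(unname(d1$m), unname(d2$m))
  expect_identical(d1$in_substudy, d2$in_substudy)
  for (i in 1:2) expect_equal(sum(d1$in_substudy[d1$group == i]), 50)
  expect_identical(validate_dataset(d1), character(0))

  full <- simulate_trial(scenario_config("differential", n_per_group = 40,
                                         calib_fraction = 1), seed = 6)
  expect_true(all(full$in_substudy))
  expect_error(mask_calibration(full, 0.02), "fewer than 3")
  expect_error(scenario_config("differential", n_per_group = 500,
                               calib_fraction = 0.004), "fewer than 3")
})

test_that("skewed true intake keeps the target mean/variance and the
           biomarker estimator unbiased", {
  cfg <- scenario_config("differential", truth_distribution = "nonnormal",
                         skewness = 1.5, n_per_group = 100000,
                         calib_fraction = 1)
  d <- simulate_trial(cfg, seed = 7)
  t_true <- attr(d, "t_true")
  for (i in 1:2) {
    ti <- t_true[d$group == i]
    mu <- c(4.6, 4.1)[i]
    expect_lt(abs(mean(ti) - mu), 3 * sd(ti) / sqrt(length(ti)))
    expect_equal(var(ti), 0.1, tolerance = 0.03)
    sk <- mean((ti - mean(ti))^3) / sd(ti)^3
    expect_equal(sk, 1.5, tolerance = 0.15)
  }

  # skewness 0 falls back to the identical normal draw
  cfg_n <- scenario_config("differential", truth_distribution = "nonnormal",
                           skewness = 0, n_per_group = 200,
                           calib_fraction = 1)
  cfg_0 <- scenario_config("differential", n_per_group = 200,
                           calib_fraction = 1)
  expect_identical(simulate_trial(cfg_n, seed = 8)$q,
                   simulate_trial(cfg_0, seed = 8)$q)

  # classical-error unbiasedness of the biomarker estimator, skewed truth
  cfg_s <- scenario_config("differential", truth_distribution = "nonnormal",
                           skewness = 1.5, n_per_group = 200,
                           calib_fraction = 0.5)
  set.seed(9)
  seeds <- sample.int(2^31 - 2, 300)
  est <- vapply(seeds, function(s)
    estimate_theta_bio(simulate_trial(cfg_s, seed = s))$estimate, numeric(1))
  expect_lt(abs(mean(est) + 0.5), 3 * sd(est) / sqrt(length(est)))
})

test_that("scenario configuration validates its inputs", {
  expect_error(scenario_config("differential", sigma2_T = -1), "non-negative")
  expect_error(scenario_config("differential", calib_fraction = 0), "0, 1")
  expect_error(scenario_config("differential", calib_fraction = 1.2), "0, 1")
  cfg <- scenario_config("nondifferential")
  expect_equal(cfg$alpha0, c(0.9, 0.9))
  expect_equal(cfg$alpha1, c(0.65, 0.65))
  cfg2 <- scenario_config("differential", sigma2_Q = 0.3)
  expect_equal(cfg2$sigma2_Q, c(0.3, 0.3))
})
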