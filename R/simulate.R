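# Synthetic two-arm trial generator: true intake T per group, one
# self-report Q linear in T with group-specific (or shared) intercept and
# slope, two classical-error biomarker replicates, and masking of the
# biomarkers outside a randomly selected calibration sub-study.

#' Scenario configuration for the trial generator
#'
#' Collects the generator parameters.  The defaults are the reference
#' operating conditions used throughout the package's simulation studies:
#' true-intake means `(4.6, 4.1)` (intervention effect -0.5), true-intake
#' variance 0.1 and biomarker error variance 0.2 in both groups, self-report
#' error variance 0.09 in both groups, 500 individuals per group, and a 10%
#' calibration sub-study.  The self-report coefficients default to
#' `alpha0 = (0.3, 1.5)`, `alpha1 = (0.8, 0.5)` under differential error
#' and to the shared `alpha0 = 0.9`, `alpha1 = 0.65` under non-differential
#' error.
#'
#' @param error_structure generator error structure; selects the default
#'   `alpha0`/`alpha1`.
#' @param muT true-intake means, length 2.
#' @param alpha0,alpha1 self-report intercepts and slopes, length 2 (or
#'   scalars, recycled); override the structure defaults.
#' @param sigma2_T,sigma2_M,sigma2_Q variances of true intake, biomarker
#'   error, self-report error; length 2 or scalar.
#' @param n_per_group individuals per group.
#' @param calib_fraction fraction of each group in the calibration
#'   sub-study, in (0, 1]; `n_per_group * calib_fraction` must be >= 3.
#' @param truth_distribution `"normal"` or `"nonnormal"` (shift/scaled
#'   gamma with the target mean and variance).
#' @param skewness skewness of true intake under `"nonnormal"`; 0 falls
#'   back to the normal generator.  Default 1 (moderate right skew).
#' @param n_reps default number of Monte-Carlo replicates for study
#'   runners.
#' @param seed optional default master seed for study runners.
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' scenario_config("differential", sigma2_Q = 0.3, calib_fraction = 0.25)
scenario_config <- function(error_structure = c("differential",
                                                "nondifferential"),
                            muT = c(4.6, 4.1),
                            alpha0 = NULL, alpha1 = NULL,
                            sigma2_T = 0.1, sigma2_M = 0.2, sigma2_Q = 0.09,
                            n_per_group = 500, calib_fraction = 0.10,
                            truth_distribution = c("normal", "nonnormal"),
                            skewness = 1,
                            n_reps = 1000, seed = NULL) {
  error_structure <- match.arg(error_structure)
  truth_distribution <- match.arg(truth_distribution)
  if (is.null(alpha0)) {
    alpha0 <- if (error_structure == "differential") c(0.3, 1.5) else
      c(0.9, 0.9)
  }
  if (is.null(alpha1)) {
    alpha1 <- if (error_structure == "differential") c(0.8, 0.5) else
      c(0.65, 0.65)
  }
  cfg <- list(error_structure = error_structure,
              muT = rep_len(muT, 2L),
              alpha0 = rep_len(alpha0, 2L), alpha1 = rep_len(alpha1, 2L),
              sigma2_T = rep_len(sigma2_T, 2L),
              sigma2_M = rep_len(sigma2_M, 2L),
              sigma2_Q = rep_len(sigma2_Q, 2L),
              n_per_group = as.integer(n_per_group),
              calib_fraction = calib_fraction,
              truth_distribution = truth_distribution,
              skewness = skewness,
              n_reps = as.integer(n_reps), seed = seed)
  if (any(!is.finite(unlist(cfg[c("muT", "alpha0", "alpha1", "sigma2_T",
                                  "sigma2_M", "sigma2_Q")]))))
    stop("non-finite scenario parameters")
  if (any(c(cfg$sigma2_T, cfg$sigma2_M, cfg$sigma2_Q) < 0))
    stop("variances must be non-negative")
  if (cfg$calib_fraction <= 0 || cfg$calib_fraction > 1)
    stop("calib_fraction must be in (0, 1]")
  if (round(cfg$calib_fraction * cfg$n_per_group) < 3)
    stop("calibration sub-study would have fewer than 3 members per group")
  if (!is.finite(cfg$skewness))
    stop("skewness must be finite")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario: ", x$error_structure, " error, ",
      x$truth_distribution, " true intake\n", sep = "")
  cat(sprintf("  muT = (%g, %g); alpha0 = (%g, %g); alpha1 = (%g, %g)\n",
              x$muT[1], x$muT[2], x$alpha0[1], x$alpha0[2],
              x$alpha1[1], x$alpha1[2]))
  cat(sprintf("  sigma2_T = (%g, %g); sigma2_M = (%g, %g); sigma2_Q = (%g, %g)\n",
              x$sigma2_T[1], x$sigma2_T[2], x$sigma2_M[1], x$sigma2_M[2],
              x$sigma2_Q[1], x$sigma2_Q[2]))
  cat(sprintf("  n_per_group = %d, calibration fraction = %g, n_reps = %d\n",
              x$n_per_group, x$calib_fraction, x$n_reps))
  invisible(x)
}

# True intake draws: normal, or gamma shifted/scaled to the target mean and
# variance with the requested skewness (shape k = 4/skewness^2).
draw_truth <- function(n, mu, s2, truth, skewness) {
  if (truth == "normal" || skewness == 0)
    return(stats::rnorm(n, mu, sqrt(s2)))
  k <- 4 / skewness^2
  z <- (stats::rgamma(n, shape = k, scale = 1) - k) / sqrt(k)
  if (skewness < 0) z <- -z
  mu + sqrt(s2) * z
}

#' Simulate a calibration trial
#'
#' Draws `2 * n_per_group` individuals: true intake `T` from the group's
#' intake distribution, self-report `Q = alpha0 + alpha1 T + e_Q`, and two
#' biomarker replicates `Mk = T + e_Mk`, then masks the biomarkers outside
#' a random calibration sub-study of `round(calib_fraction * n_per_group)`
#' individuals per group (stratified, so the sub-study size per arm is
#' fixed).  The unmasked biomarker matrix and the latent true intakes are
#' retained as attributes `m_full` and `t_true` for gold-standard
#' comparisons.
#'
#' @param cfg a [scenario_config()].
#' @param seed optional integer; when supplied, the RNG is seeded so the
#'   dataset (including the mask) is exactly reproducible.
#' @return A [trial_dataset()] with attributes `m_full`, `t_true` and
#'   `true_effect` (`muT2 - muT1`).
#' @export
simulate_trial <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_per_group
  group <- rep(1:2, each = n)
  t_true <- q <- m1 <- m2 <- numeric(2 * n)
  for (i in 1:2) {
    idx <- which(group == i)
    ti <- draw_truth(n, cfg$muT[i], cfg$sigma2_T[i],
                     cfg$truth_distribution, cfg$skewness)
    t_true[idx] <- ti
    q[idx] <- cfg$alpha0[i] + cfg$alpha1[i] * ti +
      stats::rnorm(n, 0, sqrt(cfg$sigma2_Q[i]))
    m1[idx] <- ti + stats::rnorm(n, 0, sqrt(cfg$sigma2_M[i]))
    m2[idx] <- ti + stats::rnorm(n, 0, sqrt(cfg$sigma2_M[i]))
  }
  full <- new_trial_dataset(group, q, cbind(m1, m2))
  d <- if (cfg$calib_fraction < 1)
    mask_calibration(full, cfg$calib_fraction) else full
  attr(d, "m_full") <- full$m
  attr(d, "t_true") <- t_true
  attr(d, "true_effect") <- cfg$muT[2] - cfg$muT[1]
  d
}

#' Mask biomarkers outside a random calibration sub-study
#'
#' Within each group independently, keeps the biomarker replicates for a
#' simple random sample of `round(fraction * N_i)` individuals and sets all
#' replicates of the others to missing.  Stratifying by group keeps the
#' per-arm sub-study size non-random.
#'
#' @param d a [trial_dataset()] (typically fully observed).
#' @param fraction sub-study fraction in (0, 1].
#' @return The masked `trial_dataset`.
#' @export
mask_calibration <- function(d, fraction) {
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  m <- d$m
  for (i in 1:2) {
    idx <- which(d$group == i)
    keep_n <- round(fraction * length(idx))
    if (keep_n < 3)
      stop("masking would leave fewer than 3 sub-study members in group ", i)
    drop <- setdiff(idx, sample(idx, keep_n))
    m[drop, ] <- NA_real_
  }
  new_trial_dataset(d$group, d$q, m)
}
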