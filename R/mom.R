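# Method-of-moments estimation of the intervention effect on an
# error-prone outcome, and the inverse-variance-weighted (Buonaccorsi)
# combination of the biomarker-only and self-report-based estimators.
#
# Notation per group i (1 = control, 2 = intervention): N_i individuals,
# n_i of them in the calibration sub-study with replicates M_ij1, M_ij2;
# Mbar_ij = (M_ij1 + M_ij2)/2; Qbar_i is the full-sample self-report mean,
# Qbar_is the sub-study self-report mean, Mbar_i the sub-study mean of
# Mbar_ij.  The two component estimators of the effect muT2 - muT1 are
#   theta_bio = Mbar_2 - Mbar_1                              (biomarkers only)
#   theta_sr  = (Qbar_2 - Qbar_2s)/a12 - (Qbar_1 - Qbar_1s)/a11 + theta_bio
#               (differential), or (Qbar_2 - Qbar_1)/a1 (non-differential),
# with slopes a1i = cov(Q, Mbar)/cov(M1, M2) from the sub-study (pooled
# across groups in the non-differential case).
#
# The MoM path only ever uses the first two replicate columns; additional
# columns are carried by the container but ignored here.

mom_error_structures <- c("differential", "nondifferential")

# Per-group and pooled first/second sub-study moments (n-1 denominators).
# Sub-study members must have both m1 and m2 observed.
mom_moments <- function(d) {
  g <- lapply(1:2, function(i) {
    gi <- d$group == i
    sub <- gi & d$in_substudy
    m1 <- d$m[sub, 1L]
    m2 <- d$m[sub, 2L]
    if (anyNA(m1) || anyNA(m2))
      stop("sub-study members must have replicates m1 and m2 observed ",
           "for method-of-moments estimation")
    qs <- d$q[sub]
    mbar <- (m1 + m2) / 2
    list(N = sum(gi), n = sum(sub),
         q = d$q[gi], qs = qs, m1 = m1, m2 = m2, mbar = mbar,
         qbar = mean(d$q[gi]), qbar_s = mean(qs), Mbar = mean(mbar),
         cQM = if (sum(sub) >= 2) stats::cov(qs, mbar) else NA_real_,
         cMM = if (sum(sub) >= 2) stats::cov(m1, m2) else NA_real_,
         var_q_full = stats::var(d$q[gi]),
         var_q_sub = stats::var(qs),
         var_m_all = (stats::var(m1) + stats::var(m2)) / 2,
         var_mbar = stats::var(mbar))
  })
  qs <- c(g[[1]]$qs, g[[2]]$qs)
  m1 <- c(g[[1]]$m1, g[[2]]$m1)
  m2 <- c(g[[1]]$m2, g[[2]]$m2)
  mbar <- (m1 + m2) / 2
  pooled <- list(
    n = length(qs), qbar_s = mean(qs), Mbar = mean(mbar),
    cQM = stats::cov(qs, mbar), cMM = stats::cov(m1, m2),
    var_q_sub = stats::var(qs),
    var_m_all = (stats::var(m1) + stats::var(m2)) / 2)
  list(group = g, pooled = pooled)
}

#' Biomarker-only estimator of the intervention effect
#'
#' The difference of sub-study means of the per-individual biomarker
#' replicate averages, `Mbar_2 - Mbar_1`.  Because the biomarker follows the
#' classical error model, this is unbiased for the intervention effect
#' `muT2 - muT1` regardless of the self-report error structure.  Its
#' variance is estimated by the sample variance (n - 1 denominator) of the
#' per-individual means within each group, divided by the sub-study size.
#'
#' @param d a [trial_dataset()] with at least 2 sub-study members per group.
#' @return List with `estimate`, `variance`, and sub-study sizes `n`.
#' @export
estimate_theta_bio <- function(d) {
  mm <- mom_moments(d)$group
  if (mm[[1]]$n < 2L || mm[[2]]$n < 2L)
    stop("estimate_theta_bio needs >= 2 sub-study members per group")
  list(estimate = mm[[2]]$Mbar - mm[[1]]$Mbar,
       variance = mm[[1]]$var_mbar / mm[[1]]$n + mm[[2]]$var_mbar / mm[[2]]$n,
       n = c(mm[[1]]$n, mm[[2]]$n))
}

#' Method-of-moments estimators of the self-report error model
#'
#' Errors-in-variables slope and intercept of the linear self-report model
#' `Q = a0 + a1 T + error`.  The slope is `cov(Q, Mbar) / cov(M1, M2)`,
#' where `cov(M1, M2)` estimates `var(T)` under the classical biomarker
#' error model; the intercept follows as `Qbar_s - a1 Mbar`.  Under
#' differential error the covariances are computed within each group's
#' sub-study, giving group-specific `(a0i, a1i)`; under non-differential
#' error they are computed over the pooled sub-study of both groups,
#' giving a shared `(a0, a1)`.
#'
#' A non-positive replicate covariance `cov(M1, M2)` makes the slope
#' denominator degenerate; the result is still returned but flagged with
#' `valid = FALSE` so downstream fits can be excluded rather than silently
#' propagated.
#'
#' @param d a [trial_dataset()] with at least 3 sub-study members per group
#'   (differential) or 3 pooled (non-differential).
#' @param error `"differential"` or `"nondifferential"`.
#' @return An object of class `mom_alphas`: list with `error`, `alpha0`,
#'   `alpha1` (length 2, or length 1 when pooled), the covariances used,
#'   and `valid`.
#' @export
estimate_alphas <- function(d, error = c("differential", "nondifferential")) {
  error <- match.arg(error)
  mm <- mom_moments(d)
  if (error == "differential") {
    if (mm$group[[1]]$n < 3L || mm$group[[2]]$n < 3L)
      stop("differential error-model estimation needs >= 3 sub-study ",
           "members per group")
    cQM <- vapply(mm$group, `[[`, numeric(1), "cQM")
    cMM <- vapply(mm$group, `[[`, numeric(1), "cMM")
    alpha1 <- cQM / cMM
    alpha0 <- vapply(1:2, function(i)
      mm$group[[i]]$qbar_s - alpha1[i] * mm$group[[i]]$Mbar, numeric(1))
  } else {
    if (mm$pooled$n < 3L)
      stop("non-differential error-model estimation needs >= 3 pooled ",
           "sub-study members")
    cQM <- mm$pooled$cQM
    cMM <- mm$pooled$cMM
    alpha1 <- cQM / cMM
    alpha0 <- mm$pooled$qbar_s - alpha1 * mm$pooled$Mbar
  }
  structure(list(error = error, alpha0 = alpha0, alpha1 = alpha1,
                 cov_q_mbar = cQM, cov_m1_m2 = cMM,
                 valid = all(cMM > 0)),
            class = "mom_alphas")
}

#' Self-report-based estimator of the intervention effect
#'
#' The bias-corrected estimator built from the self-reports and the fitted
#' error model.  Under differential error it is
#' `(Qbar_2 - Qbar_2s)/a12 - (Qbar_1 - Qbar_1s)/a11 + Mbar_2 - Mbar_1`;
#' under non-differential error it is `(Qbar_2 - Qbar_1)/a1`, a consistent
#' estimator of the effect that does not collapse onto the biomarker-only
#' estimator as the sample grows.
#'
#' @param d a [trial_dataset()].
#' @param alphas a [estimate_alphas()] result (its `error` field selects the
#'   form of the estimator).
#' @return The point estimate (numeric scalar).
#' @export
estimate_theta_sr <- function(d, alphas) {
  if (!inherits(alphas, "mom_alphas")) stop("`alphas` must be a mom_alphas")
  if (any(!is.finite(alphas$alpha1)) || any(alphas$alpha1 == 0))
    stop("undefined self-report estimator: slope estimate is 0 or non-finite")
  mm <- mom_moments(d)$group
  if (alphas$error == "differential") {
    (mm[[2]]$qbar - mm[[2]]$qbar_s) / alphas$alpha1[2] -
      (mm[[1]]$qbar - mm[[1]]$qbar_s) / alphas$alpha1[1] +
      mm[[2]]$Mbar - mm[[1]]$Mbar
  } else {
    (mm[[2]]$qbar - mm[[1]]$qbar) / alphas$alpha1
  }
}

#' Method-of-moments measurement-error variance estimates
#'
#' Biomarker error variance `var(M) - cov(M1, M2)` (with `var(M)` the
#' average of the two per-replicate sample variances, so the estimate is
#' exactly zero for error-free replicates) and self-report error variance
#' `var(Q) - a1^2 cov(M1, M2)`.  Under differential error both are
#' computed per group, with `var(Q)` taken over the group's full sample;
#' under non-differential error all moments are pooled over the combined
#' sub-study of the two groups (the between-group mean difference then
#' inflates `var(Q)` and `a1^2 cov(M1, M2)` consistently, so the difference
#' still estimates the error variance).  Negative estimates are returned
#' as-is but flagged.
#'
#' @param d a [trial_dataset()].
#' @param alphas a [estimate_alphas()] result.
#' @return List with `sigma2_M`, `sigma2_Q` (length 2 or 1) and `valid`
#'   (`FALSE` if any estimate is negative).
#' @export
estimate_error_variances <- function(d, alphas) {
  if (!inherits(alphas, "mom_alphas")) stop("`alphas` must be a mom_alphas")
  mm <- mom_moments(d)
  if (alphas$error == "differential") {
    sigma2_M <- vapply(1:2, function(i)
      mm$group[[i]]$var_m_all - mm$group[[i]]$cMM, numeric(1))
    sigma2_Q <- vapply(1:2, function(i)
      mm$group[[i]]$var_q_full - alphas$alpha1[i]^2 * mm$group[[i]]$cMM,
      numeric(1))
  } else {
    sigma2_M <- mm$pooled$var_m_all - mm$pooled$cMM
    sigma2_Q <- mm$pooled$var_q_sub - alphas$alpha1^2 * mm$pooled$cMM
  }
  list(sigma2_M = sigma2_M, sigma2_Q = sigma2_Q,
       valid = all(c(sigma2_M, sigma2_Q) >= 0))
}

#' Inverse-variance-weighted combination of two correlated estimators
#'
#' Combines the biomarker-only and self-report-based effect estimators with
#' the weights that minimize the variance of the combination given their
#' variances and covariance: the weight on the biomarker estimator is
#' `w = (var_sr - cov) / (var_bio + var_sr - 2 cov)`, the combined variance
#' `(var_bio * var_sr - cov^2) / (var_bio + var_sr - 2 cov)`.  Weights are
#' not clipped to `[0, 1]`: with a large covariance the optimal weight can
#' fall outside the unit interval.
#'
#' When the two estimators coincide (as they do at 100% calibration under
#' differential error) the weight denominator degenerates; the combination
#' then falls back to the biomarker estimator with its own variance.  A
#' non-positive-definite input matrix yields `valid = FALSE`.
#'
#' @param theta_bio,theta_sr the two point estimates.
#' @param var_bio,var_sr,cov_bio_sr their variances and covariance.
#' @return List with `estimate`, `variance`, `se`, `weight_bio`, `valid`.
#' @export
#' @examples
#' combine_estimates(0.1, 0.3, var_bio = 1, var_sr = 2, cov_bio_sr = 0.5)
combine_estimates <- function(theta_bio, theta_sr, var_bio, var_sr,
                              cov_bio_sr) {
  denom <- var_bio + var_sr - 2 * cov_bio_sr
  scale <- max(var_bio, var_sr, abs(cov_bio_sr))
  if (is.finite(denom) && denom <= 1e-12 * scale) {
    # degenerate: the two estimators are (numerically) the same statistic
    same <- abs(theta_sr - theta_bio) <= 1e-6 * max(1, abs(theta_bio))
    return(list(estimate = theta_bio, variance = var_bio,
                se = sqrt(var_bio), weight_bio = 1,
                valid = same && var_bio > 0))
  }
  pd <- var_bio > 0 && var_sr > 0 && var_bio * var_sr > cov_bio_sr^2
  w <- (var_sr - cov_bio_sr) / denom
  v <- (var_bio * var_sr - cov_bio_sr^2) / denom
  list(estimate = w * theta_bio + (1 - w) * theta_sr,
       variance = v,
       se = if (pd && v > 0) sqrt(v) else NA_real_,
       weight_bio = w,
       valid = pd && v > 0)
}

# Stacked estimating-equation sandwich for the 2x2 variance matrix of
# (theta_bio, theta_sr).  One estimating equation per moment parameter:
# full-sample Q mean, sub-study Q mean, sub-study mean of Mbar, cov(Q, Mbar)
# and cov(M1, M2) -- per group under differential error, pooled under
# non-differential (plus the two full-sample Q means and the two group
# sub-study Mbar means).  At the solution (n-denominator moments) the
# averaged-derivative matrix A is diagonal, so the sandwich A^-1 B A^-1 / N
# is computed in closed form; the delta method then maps it through the
# estimator formulas.  A small-sample factor n/(n-1) per group (pooled
# under non-differential) makes var(theta_bio) match the n-1 convention of
# estimate_theta_bio exactly.
mom_theta_vcov <- function(d, alphas) {
  if (alphas$error == "differential") {
    V <- matrix(0, 2, 2)
    for (i in 1:2) {
      gi <- d$group == i
      sub <- d$in_substudy[gi]
      q <- d$q[gi]
      m1 <- d$m[gi, 1L][sub]
      m2 <- d$m[gi, 2L][sub]
      qs <- q[sub]
      mbar <- (m1 + m2) / 2
      Ni <- length(q); ni <- length(qs)
      muQ <- mean(q); muQs <- mean(qs); muM <- mean(mbar)
      cQM <- mean((qs - muQs) * (mbar - muM))
      cMM <- mean((m1 - muM) * (m2 - muM))
      Psi <- matrix(0, Ni, 5)
      Psi[, 1] <- q - muQ
      Psi[sub, 2] <- qs - muQs
      Psi[sub, 3] <- mbar - muM
      Psi[sub, 4] <- (qs - muQs) * (mbar - muM) - cQM
      Psi[sub, 5] <- (m1 - muM) * (m2 - muM) - cMM
      B <- crossprod(Psi) / Ni
      ainv <- c(1, rep(Ni / ni, 4))
      Vi <- (B * outer(ainv, ainv)) / Ni
      alpha <- cQM / cMM
      delta <- muQ - muQs
      s <- if (i == 2) 1 else -1
      G <- rbind(s * c(0, 0, 1, 0, 0),
                 s * c(1 / alpha, -1 / alpha, 1,
                       -delta * cMM / cQM^2, delta / cQM))
      V <- V + (ni / (ni - 1)) * G %*% Vi %*% t(G)
    }
  } else {
    sub <- d$in_substudy
    g <- d$group
    q <- d$q
    m1 <- d$m[, 1L]; m2 <- d$m[, 2L]
    N <- length(q)
    N1 <- sum(g == 1); N2 <- sum(g == 2)
    n1 <- sum(sub & g == 1); n2 <- sum(sub & g == 2); n <- n1 + n2
    mbar <- (m1 + m2) / 2
    muQ1 <- mean(q[g == 1]); muQ2 <- mean(q[g == 2])
    muM1 <- mean(mbar[sub & g == 1]); muM2 <- mean(mbar[sub & g == 2])
    muQs <- mean(q[sub]); muMp <- mean(mbar[sub])
    cQM <- mean((q[sub] - muQs) * (mbar[sub] - muMp))
    cMM <- mean((m1[sub] - muMp) * (m2[sub] - muMp))
    Psi <- matrix(0, N, 8)
    Psi[g == 1, 1] <- q[g == 1] - muQ1
    Psi[g == 2, 2] <- q[g == 2] - muQ2
    Psi[sub & g == 1, 3] <- mbar[sub & g == 1] - muM1
    Psi[sub & g == 2, 4] <- mbar[sub & g == 2] - muM2
    Psi[sub, 5] <- q[sub] - muQs
    Psi[sub, 6] <- mbar[sub] - muMp
    Psi[sub, 7] <- (q[sub] - muQs) * (mbar[sub] - muMp) - cQM
    Psi[sub, 8] <- (m1[sub] - muMp) * (m2[sub] - muMp) - cMM
    B <- crossprod(Psi) / N
    ainv <- N / c(N1, N2, n1, n2, n, n, n, n)
    V8 <- (B * outer(ainv, ainv)) / N
    alpha <- cQM / cMM
    Dq <- muQ2 - muQ1
    G <- rbind(c(0, 0, -1, 1, 0, 0, 0, 0),
               c(-1 / alpha, 1 / alpha, 0, 0, 0, 0,
                 -Dq * cMM / cQM^2, Dq / cQM))
    V <- (n / (n - 1)) * G %*% V8 %*% t(G)
  }
  dimnames(V) <- list(c("theta_bio", "theta_sr"),
                      c("theta_bio", "theta_sr"))
  V
}

#' Method-of-moments fit of the intervention effect
#'
#' Runs the full method-of-moments analysis: the biomarker-only estimator,
#' the error-model parameters, the self-report-based estimator, the
#' estimating-equation variance matrix of the two estimators, and their
#' inverse-variance-weighted (Buonaccorsi) combination.
#'
#' The fit is flagged `valid = FALSE` (never an error) when any moment
#' quantity it relies on is degenerate: non-positive replicate covariance
#' `cov(M1, M2)`, a negative error-variance estimate, or a
#' non-positive-definite variance matrix of the two estimators.  Simulation
#' drivers drop invalid fits and report how many were retained.
#'
#' @param d a [trial_dataset()].
#' @param error assumed self-report error structure, `"differential"` or
#'   `"nondifferential"`.
#' @return An object of class `mom_fit` with fields `theta_bio`, `theta_sr`,
#'   `var_bio`, `var_sr`, `cov_bio_sr`, `alpha0`, `alpha1`, `sigma2_M`,
#'   `sigma2_Q`, `weight_bio`, `theta_combined`, `se_combined`, `valid`,
#'   `invalid_reasons`, `error` and sample sizes `N`, `n`.
#' @seealso [ml_fit()] for the maximum-likelihood analogue.
#' @export
#' @examples
#' cfg <- scenario_config("differential", calib_fraction = 0.25)
#' d <- simulate_trial(cfg, seed = 1)
#' mom_fit(d, "differential")
mom_fit <- function(d, error = c("differential", "nondifferential")) {
  error <- match.arg(error)
  sz <- group_sizes(d)
  alphas <- estimate_alphas(d, error)
  bio <- estimate_theta_bio(d)
  theta_sr <- estimate_theta_sr(d, alphas)
  ev <- estimate_error_variances(d, alphas)
  V <- mom_theta_vcov(d, alphas)
  comb <- combine_estimates(bio$estimate, theta_sr,
                            V[1, 1], V[2, 2], V[1, 2])
  reasons <- character(0)
  if (!alphas$valid)
    reasons <- c(reasons, "non-positive replicate covariance cov(M1,M2)")
  if (!ev$valid)
    reasons <- c(reasons, "negative error-variance estimate")
  if (!comb$valid)
    reasons <- c(reasons, "non-positive-definite estimator variance matrix")
  structure(
    list(error = error,
         theta_bio = bio$estimate, var_bio = V[1, 1],
         theta_sr = theta_sr, var_sr = V[2, 2], cov_bio_sr = V[1, 2],
         alpha0 = alphas$alpha0, alpha1 = alphas$alpha1,
         sigma2_M = ev$sigma2_M, sigma2_Q = ev$sigma2_Q,
         weight_bio = comb$weight_bio,
         theta_combined = comb$estimate,
         var_combined = comb$variance,
         se_combined = comb$se,
         valid = length(reasons) == 0L,
         invalid_reasons = reasons,
         N = sz$N, n = sz$n),
    class = "mom_fit")
}

#' @export
print.mom_fit <- function(x, digits = 4, ...) {
  cat("Method-of-moments fit (", x$error, " error)\n", sep = "")
  cat(sprintf("  N = %d + %d, sub-study n = %d + %d\n",
              x$N[1], x$N[2], x$n[1], x$n[2]))
  cat(sprintf("  biomarkers only:   %s (SE %s)\n",
              format(x$theta_bio, digits = digits),
              format(sqrt(x$var_bio), digits = digits)))
  cat(sprintf("  self-report based: %s (SE %s)\n",
              format(x$theta_sr, digits = digits),
              format(sqrt(x$var_sr), digits = digits)))
  cat(sprintf("  combined:          %s (SE %s), weight on biomarkers %s\n",
              format(x$theta_combined, digits = digits),
              format(x$se_combined, digits = digits),
              format(x$weight_bio, digits = digits)))
  if (!x$valid)
    cat("  INVALID: ", paste(x$invalid_reasons, collapse = "; "), "\n",
        sep = "")
  invisible(x)
}

# Flat key-value view of a fit, for JSON/CSV reports.
mom_fit_report <- function(x) {
  out <- list(method = "mom", error = x$error,
              theta_bio = x$theta_bio, se_bio = sqrt(x$var_bio),
              theta_sr = x$theta_sr, se_sr = sqrt(x$var_sr),
              cov_bio_sr = x$cov_bio_sr,
              theta_combined = x$theta_combined,
              se_combined = x$se_combined,
              weight_bio = x$weight_bio,
              valid = x$valid)
  lab <- if (x$error == "differential") c("1", "2") else ""
  out[paste0("alpha0_", lab)] <- as.list(x$alpha0)
  out[paste0("alpha1_", lab)] <- as.list(x$alpha1)
  out[paste0("sigma2_M_", lab)] <- as.list(x$sigma2_M)
  out[paste0("sigma2_Q_", lab)] <- as.list(x$sigma2_Q)
  names(out) <- sub("_$", "", names(out))
  out
}
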