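# Maximum-likelihood estimation of the joint measurement model.  Within
# group i, a sub-study member's (M1, M2, Q) is trivariate normal with mean
# (muTi, muTi, a0i + a1i muTi) and covariance built from (sigma2_Ti,
# sigma2_Mi, sigma2_Qi, a1i); an individual outside the sub-study
# contributes a univariate normal Q with mean a0i + a1i muTi and variance
# a1i^2 sigma2_Ti + sigma2_Qi.  Groups are independent, so the likelihood
# factorizes by group; the full 6-variate mean/covariance across both
# groups is block-diagonal and algebraically identical.

ml_par_names <- c("muT1", "muT2", "sigma2_T1", "sigma2_T2",
                  "sigma2_M1", "sigma2_M2", "sigma2_Q1", "sigma2_Q2",
                  "alpha0_1", "alpha1_1", "alpha0_2", "alpha1_2")
ml_var_names <- ml_par_names[3:8]

#' Implied per-group moments of (M1, M2, Q)
#'
#' The mean vector and covariance matrix of a sub-study member's
#' observation vector `(M1, M2, Q)` implied by the measurement model:
#' mean `(muT, muT, alpha0 + alpha1 muT)`; `var(Mk) = sigma2_T + sigma2_M`,
#' `cov(M1, M2) = sigma2_T`, `cov(Mk, Q) = alpha1 sigma2_T`,
#' `var(Q) = alpha1^2 sigma2_T + sigma2_Q`.
#'
#' @param muT,sigma2_T,sigma2_M,sigma2_Q,alpha0,alpha1 model parameters;
#'   each a vector of length 2 (group 1, group 2) or a scalar recycled to
#'   both groups.
#' @return List of two lists (one per group) with elements `mean` (length
#'   3) and `cov` (3 x 3).
#' @export
#' @examples
#' implied_moments(muT = c(4.6, 4.1), sigma2_T = 0.1, sigma2_M = 0.2,
#'                 sigma2_Q = 0.3, alpha0 = c(0.3, 1.5),
#'                 alpha1 = c(0.8, 0.5))
implied_moments <- function(muT, sigma2_T, sigma2_M, sigma2_Q,
                            alpha0, alpha1) {
  p <- lapply(list(muT = muT, sigma2_T = sigma2_T, sigma2_M = sigma2_M,
                   sigma2_Q = sigma2_Q, alpha0 = alpha0, alpha1 = alpha1),
              rep_len, 2L)
  if (any(p$sigma2_T < 0) || any(p$sigma2_M < 0) || any(p$sigma2_Q < 0))
    stop("variance parameters must be non-negative")
  lapply(1:2, function(i) {
    vT <- p$sigma2_T[i]; a1 <- p$alpha1[i]
    list(mean = c(p$muT[i], p$muT[i], p$alpha0[i] + a1 * p$muT[i]),
         cov = matrix(c(vT + p$sigma2_M[i], vT, a1 * vT,
                        vT, vT + p$sigma2_M[i], a1 * vT,
                        a1 * vT, a1 * vT, a1^2 * vT + p$sigma2_Q[i]),
                      3, 3))
  })
}

# --- parameter bookkeeping -------------------------------------------------

# Free parameter names under the constraint set; constrained entries are
# copies of their group-1 counterpart.
ml_free_names <- function(error, equal_sigma_T, equal_sigma_M,
                          equal_sigma_Q) {
  drop <- character(0)
  if (error == "nondifferential") drop <- c(drop, "alpha0_2", "alpha1_2")
  if (equal_sigma_T) drop <- c(drop, "sigma2_T2")
  if (equal_sigma_M) drop <- c(drop, "sigma2_M2")
  if (equal_sigma_Q) drop <- c(drop, "sigma2_Q2")
  setdiff(ml_par_names, drop)
}

# Expand a named free vector to the full 12-parameter named vector.
ml_expand <- function(free) {
  full <- stats::setNames(numeric(12), ml_par_names)
  full[names(free)] <- free
  if (!"alpha0_2" %in% names(free)) full["alpha0_2"] <- free["alpha0_1"]
  if (!"alpha1_2" %in% names(free)) full["alpha1_2"] <- free["alpha1_1"]
  if (!"sigma2_T2" %in% names(free)) full["sigma2_T2"] <- free["sigma2_T1"]
  if (!"sigma2_M2" %in% names(free)) full["sigma2_M2"] <- free["sigma2_M1"]
  if (!"sigma2_Q2" %in% names(free)) full["sigma2_Q2"] <- free["sigma2_Q1"]
  full
}

# --- likelihood ------------------------------------------------------------

# Sufficient statistics: per group, sub-study sample mean and (ML, /n)
# scatter of (M1, M2, Q), and outside-sub-study mean and (ML) variance of Q.
ml_suff_stats <- function(d) {
  lapply(1:2, function(i) {
    gi <- d$group == i
    sub <- gi & d$in_substudy
    X <- cbind(d$m[sub, 1L], d$m[sub, 2L], d$q[sub])
    if (anyNA(X))
      stop("sub-study members must have replicates m1 and m2 observed ",
           "for maximum-likelihood estimation")
    ns <- nrow(X)
    xbar <- colMeans(X)
    S <- crossprod(sweep(X, 2L, xbar)) / ns
    qo <- d$q[gi & !d$in_substudy]
    no <- length(qo)
    list(ns = ns, xbar = xbar, S = S, no = no,
         qbar_o = if (no) mean(qo) else 0,
         qvar_o = if (no) mean((qo - mean(qo))^2) else 0)
  })
}

# Negative log-likelihood from a full named parameter vector.
ml_nll <- function(full, st) {
  tot <- 0
  for (i in 1:2) {
    vT <- full[[paste0("sigma2_T", i)]]
    vM <- full[[paste0("sigma2_M", i)]]
    vQ <- full[[paste0("sigma2_Q", i)]]
    a0 <- full[[paste0("alpha0_", i)]]
    a1 <- full[[paste0("alpha1_", i)]]
    muT <- full[[paste0("muT", i)]]
    if (!all(is.finite(c(vT, vM, vQ, a0, a1, muT))) ||
        vT <= 0 || vM <= 0 || vQ <= 0)
      return(1e10)
    mu <- c(muT, muT, a0 + a1 * muT)
    Sig <- matrix(c(vT + vM, vT, a1 * vT,
                    vT, vT + vM, a1 * vT,
                    a1 * vT, a1 * vT, a1^2 * vT + vQ), 3, 3)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Sinv <- chol2inv(ch)
    s <- st[[i]]
    dmu <- s$xbar - mu
    tot <- tot + s$ns / 2 *
      (3 * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(Sinv * s$S) +
         drop(crossprod(dmu, Sinv %*% dmu)))
    if (s$no > 0) {
      vstar <- a1^2 * vT + vQ
      tot <- tot + s$no / 2 *
        (log(2 * pi * vstar) + (s$qvar_o + (s$qbar_o - a0 - a1 * muT)^2) /
           vstar)
    }
  }
  if (!is.finite(tot)) 1e10 else tot
}

# Per-individual negative log-likelihood contributions (for scores).
ml_nll_contribs <- function(full, d) {
  out <- numeric(length(d$q))
  for (i in 1:2) {
    vT <- full[[paste0("sigma2_T", i)]]
    vM <- full[[paste0("sigma2_M", i)]]
    vQ <- full[[paste0("sigma2_Q", i)]]
    a0 <- full[[paste0("alpha0_", i)]]
    a1 <- full[[paste0("alpha1_", i)]]
    muT <- full[[paste0("muT", i)]]
    mu <- c(muT, muT, a0 + a1 * muT)
    Sig <- matrix(c(vT + vM, vT, a1 * vT,
                    vT, vT + vM, a1 * vT,
                    a1 * vT, a1 * vT, a1^2 * vT + vQ), 3, 3)
    ch <- chol(Sig)
    Sinv <- chol2inv(ch)
    sub <- d$group == i & d$in_substudy
    X <- sweep(cbind(d$m[sub, 1L], d$m[sub, 2L], d$q[sub]), 2L, mu)
    out[sub] <- 0.5 * (3 * log(2 * pi) + 2 * sum(log(diag(ch))) +
                         rowSums((X %*% Sinv) * X))
    outp <- d$group == i & !d$in_substudy
    if (any(outp)) {
      vstar <- a1^2 * vT + vQ
      out[outp] <- 0.5 * (log(2 * pi * vstar) +
                            (d$q[outp] - a0 - a1 * muT)^2 / vstar)
    }
  }
  out
}

# Exact generalized-least-squares update of the mean parameters (muT1,
# muT2, alpha0_1, alpha0_2, with ties respected) given the current
# variance/slope parameters: the means enter the model linearly, so their
# profile optimum is a small linear solve.  This also makes degenerate
# (noise-free) fits return the group sample means exactly.
ml_profile_means <- function(full, st, tied_alpha0) {
  p <- if (tied_alpha0) 3L else 4L
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  for (i in 1:2) {
    vT <- full[[paste0("sigma2_T", i)]]
    vM <- full[[paste0("sigma2_M", i)]]
    vQ <- full[[paste0("sigma2_Q", i)]]
    a1 <- full[[paste0("alpha1_", i)]]
    idx <- c(i, if (tied_alpha0) 3L else 2L + i)  # (muTi, alpha0i)
    Sig <- matrix(c(vT + vM, vT, a1 * vT,
                    vT, vT + vM, a1 * vT,
                    a1 * vT, a1 * vT, a1^2 * vT + vQ), 3, 3)
    Sinv <- chol2inv(chol(Sig))
    A <- matrix(c(1, 0, 1, 0, a1, 1), 3, 2, byrow = TRUE)
    s <- st[[i]]
    XtX[idx, idx] <- XtX[idx, idx] + s$ns * crossprod(A, Sinv %*% A)
    Xty[idx] <- Xty[idx] + s$ns * drop(crossprod(A, Sinv %*% s$xbar))
    if (s$no > 0) {
      vstar <- a1^2 * vT + vQ
      cc <- c(a1, 1)
      XtX[idx, idx] <- XtX[idx, idx] + s$no * tcrossprod(cc) / vstar
      Xty[idx] <- Xty[idx] + s$no * cc * s$qbar_o / vstar
    }
  }
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta)) return(full)
  full["muT1"] <- beta[1]
  full["muT2"] <- beta[2]
  if (tied_alpha0) {
    full["alpha0_1"] <- full["alpha0_2"] <- beta[3]
  } else {
    full["alpha0_1"] <- beta[3]
    full["alpha0_2"] <- beta[4]
  }
  full
}

# --- fitting ---------------------------------------------------------------

ml_start <- function(d, free_names) {
  mom <- tryCatch(mom_fit(d, "differential"), error = function(e) NULL)
  mm <- mom_moments(d)$group
  full <- stats::setNames(numeric(12), ml_par_names)
  for (i in 1:2) {
    full[paste0("muT", i)] <- mm[[i]]$Mbar
    cMM <- mm[[i]]$cMM
    full[paste0("sigma2_T", i)] <-
      if (is.finite(cMM) && cMM > 1e-4) cMM else 0.5 * mm[[i]]$var_m_all
    full[paste0("sigma2_M", i)] <- max(mm[[i]]$var_m_all - cMM,
                                       0.25 * mm[[i]]$var_m_all, 1e-4)
    a1 <- if (!is.null(mom) && mom$valid) mom$alpha1[i] else 1
    if (!is.finite(a1) || abs(a1) < 0.05) a1 <- 1
    full[paste0("alpha1_", i)] <- a1
    full[paste0("alpha0_", i)] <-
      if (!is.null(mom) && mom$valid) {
        mom$alpha0[i]
      } else {
        mm[[i]]$qbar_s - a1 * mm[[i]]$Mbar
      }
    sQ <- if (!is.null(mom)) mom$sigma2_Q[i] else NA_real_
    full[paste0("sigma2_Q", i)] <-
      if (is.finite(sQ) && sQ > 1e-4) sQ else 0.5 * mm[[i]]$var_q_full
  }
  # average tied parameters so constrained starts are consistent
  if (!"alpha1_2" %in% free_names) {
    full["alpha1_1"] <- mean(full[c("alpha1_1", "alpha1_2")])
    full["alpha0_1"] <- mean(full[c("alpha0_1", "alpha0_2")])
  }
  for (nm in c("sigma2_T", "sigma2_M", "sigma2_Q")) {
    if (!paste0(nm, "2") %in% free_names)
      full[paste0(nm, "1")] <- mean(full[paste0(nm, 1:2)])
  }
  full[free_names]
}

#' Maximum-likelihood fit of the measurement model
#'
#' Maximizes the full likelihood: the product of trivariate-normal
#' densities of `(M1, M2, Q)` for calibration sub-study members and
#' univariate-normal densities of `Q` for the remaining individuals, by
#' group.  The most general (differential) model has 12 parameters:
#' `muT`, `sigma2_T`, `sigma2_M`, `sigma2_Q`, `alpha0`, `alpha1` per group.
#' `error = "nondifferential"` ties `alpha0` and `alpha1` across groups;
#' the `equal_sigma_*` flags tie the corresponding variances.
#'
#' Variances are optimized on the log scale (boundary-safe); starting
#' values come from the method-of-moments fit when valid.  Model-based
#' standard errors use the inverse observed information (numerical Hessian
#' in the natural parameterization).  The intervention effect is
#' `muT2 - muT1` with a delta-method standard error.
#'
#' @param d a [trial_dataset()].
#' @param error `"differential"` or `"nondifferential"`.
#' @param equal_sigma_T,equal_sigma_M,equal_sigma_Q tie the true-intake,
#'   biomarker-error, or self-report-error variance across groups.
#' @param start optional named vector of starting values for the free
#'   parameters (natural scale).
#' @param control passed to [stats::optim()] (method L-BFGS-B); defaults to
#'   `factr = 1e3` (relative tolerance near 1e-13), `maxit = 500`.
#' @param vcov if `FALSE`, skip the observed-information computation
#'   (point estimates only; useful in large Monte-Carlo parameter-recovery
#'   runs).
#' @return An object of class `ml_fit` with the full parameter vector
#'   (`params`), the free-parameter estimates (`free`), `loglik`,
#'   `vcov_model`, `effect`, `effect_se`, `converged`, `boundary`, and the
#'   constraint description.
#' @seealso [sandwich_vcov()], [lrt()], [mom_fit()]
#' @export
#' @examples
#' cfg <- scenario_config("nondifferential", n_per_group = 200,
#'                        calib_fraction = 0.5)
#' d <- simulate_trial(cfg, seed = 1)
#' ml_fit(d, "nondifferential")
ml_fit <- function(d, error = c("differential", "nondifferential"),
                   equal_sigma_T = FALSE, equal_sigma_M = FALSE,
                   equal_sigma_Q = FALSE, start = NULL, control = list(),
                   vcov = TRUE) {
  error <- match.arg(error)
  free_names <- ml_free_names(error, equal_sigma_T, equal_sigma_M,
                              equal_sigma_Q)
  st <- ml_suff_stats(d)
  if (st[[1]]$ns < 2L || st[[2]]$ns < 2L)
    stop("maximum-likelihood fit needs a non-empty sub-study in each group")
  if (is.null(start)) start <- ml_start(d, free_names)
  start <- start[free_names]
  tied_alpha0 <- !"alpha0_2" %in% free_names
  mean_names <- intersect(c("muT1", "muT2", "alpha0_1", "alpha0_2"),
                          free_names)
  # the mean parameters are linear in the model, so they are profiled out
  # exactly (GLS) inside the objective; the optimizer only sees the
  # variance and slope parameters, with variances on the log scale and a
  # floor that keeps the likelihood bounded on degenerate (noise-free)
  # data.  Hitting the floor is reported via `boundary`.
  prof_names <- setdiff(free_names, mean_names)
  is_var <- prof_names %in% ml_var_names
  start_means <- start[mean_names]
  assemble <- function(z) {
    th <- z
    th[is_var] <- exp(th[is_var])
    free <- c(start_means, stats::setNames(th, prof_names))[free_names]
    ml_profile_means(ml_expand(free), st, tied_alpha0)
  }
  fn <- function(z) ml_nll(assemble(z), st)
  z0 <- start[prof_names]
  z0[is_var] <- log(pmax(z0[is_var], 1e-10))
  lower <- rep(-Inf, length(z0))
  lower[is_var] <- log(1e-10)
  ctrl <- utils::modifyList(list(factr = 1e5, maxit = 500), control)
  opt <- stats::optim(z0, fn, method = "L-BFGS-B", lower = lower,
                      control = ctrl)
  full <- assemble(opt$par)
  free <- full[free_names]
  boundary <- any(free[is_var] < 1e-8)
  hess <- if (!vcov) NULL else tryCatch(
    pracma::hessian(function(th) {
      names(th) <- free_names
      ml_nll(ml_expand(th), st)
    }, free),
    error = function(e) NULL)
  vcov_model <- NULL
  if (!is.null(hess)) {
    vcov_model <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov_model))
      dimnames(vcov_model) <- list(free_names, free_names)
  }
  effect <- unname(full["muT2"] - full["muT1"])
  effect_se <- NA_real_
  ok_vcov <- !is.null(vcov_model) &&
    all(is.finite(diag(vcov_model))) && all(diag(vcov_model) > 0)
  if (ok_vcov) {
    i1 <- match("muT1", free_names); i2 <- match("muT2", free_names)
    v <- vcov_model[i1, i1] + vcov_model[i2, i2] - 2 * vcov_model[i1, i2]
    if (is.finite(v) && v > 0) effect_se <- sqrt(v)
  }
  structure(
    list(params = full, free = free, free_names = free_names,
         error = error,
         equal_sigma = c(T = equal_sigma_T, M = equal_sigma_M,
                         Q = equal_sigma_Q),
         loglik = -opt$value,
         vcov_model = vcov_model,
         hessian = hess,
         effect = effect, effect_se = effect_se,
         converged = opt$convergence == 0 &&
           (!vcov || !is.na(effect_se)),
         boundary = boundary,
         npar = length(free_names),
         n = group_sizes(d)),
    class = "ml_fit")
}

#' Sandwich (robust) variance for a maximum-likelihood fit
#'
#' Computes `A^-1 B A^-T` where `A` is the averaged negative Hessian of the
#' log-likelihood (from the fit's observed information) and `B` the
#' empirical covariance of the per-individual score contributions (central
#' differences).  The maximum-likelihood estimators depend on the data only
#' through first and second moments, so they remain consistent when the
#' data are not multivariate normal; this robust variance remains valid in
#' that case while the model-based variance may not.
#'
#' @param d the [trial_dataset()] that `fit` was estimated from.
#' @param fit a converged [ml_fit()].
#' @return The robust variance matrix of the free parameters, with an
#'   attribute `effect_se` giving the robust standard error of
#'   `muT2 - muT1`.
#' @export
sandwich_vcov <- function(d, fit) {
  if (!inherits(fit, "ml_fit")) stop("`fit` must be an ml_fit")
  if (is.null(fit$hessian))
    stop("fit has no information matrix; refit before computing the sandwich")
  free <- fit$free
  p <- length(free)
  n_ind <- length(d$q)
  scores <- matrix(0, n_ind, p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(free[j]))
    up <- free; up[j] <- up[j] + h
    dn <- free; dn[j] <- dn[j] - h
    scores[, j] <- (ml_nll_contribs(ml_expand(up), d) -
                      ml_nll_contribs(ml_expand(dn), d)) / (2 * h)
  }
  Ainv <- tryCatch(solve(fit$hessian), error = function(e)
    stop("singular information matrix; condition number ",
         format(tryCatch(kappa(fit$hessian), error = function(e) NA))))
  B <- crossprod(scores)
  V <- Ainv %*% B %*% t(Ainv)
  dimnames(V) <- list(fit$free_names, fit$free_names)
  i1 <- match("muT1", fit$free_names); i2 <- match("muT2", fit$free_names)
  v <- V[i1, i1] + V[i2, i2] - 2 * V[i1, i2]
  attr(V, "effect_se") <- if (is.finite(v) && v > 0) sqrt(v) else NA_real_
  V
}

#' Likelihood-ratio test between nested fits
#'
#' Twice the log-likelihood difference, referred to a chi-square
#' distribution.  The comparison of the differential against the
#' non-differential model (two tied parameters) has 2 degrees of freedom.
#'
#' @param fit_full,fit_restricted [ml_fit()] objects, the restricted model
#'   nested within the full one on the same data.
#' @param df degrees of freedom; defaults to the difference in free
#'   parameter counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_full, fit_restricted, df = NULL) {
  if (!inherits(fit_full, "ml_fit") || !inherits(fit_restricted, "ml_fit"))
    stop("both arguments must be ml_fit objects")
  if (is.null(df)) df <- fit_full$npar - fit_restricted$npar
  if (df < 1L) stop("restricted model must have fewer free parameters")
  stat <- 2 * (fit_full$loglik - fit_restricted$loglik)
  if (stat < -1e-6 * max(1, abs(fit_full$loglik)))
    stop("negative likelihood-ratio statistic (", format(stat),
         "): one of the fits has not converged")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Wald test of differential error
#'
#' Joint Wald test that the self-report error model is the same in both
#' groups (`alpha0_1 = alpha0_2`, `alpha1_1 = alpha1_2`), based on a fitted
#' differential-error model and its variance matrix (model-based by
#' default; pass the [sandwich_vcov()] result for a robust test).
#'
#' @param fit a differential-error [ml_fit()].
#' @param vcov variance matrix of the free parameters; defaults to the
#'   model-based one.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
wald_differential <- function(fit, vcov = fit$vcov_model) {
  if (!inherits(fit, "ml_fit") || fit$error != "differential")
    stop("`fit` must be a differential-error ml_fit")
  idx <- match(c("alpha0_1", "alpha0_2", "alpha1_1", "alpha1_2"),
               fit$free_names)
  L <- matrix(0, 2, length(fit$free_names))
  L[1, idx[1]] <- 1; L[1, idx[2]] <- -1
  L[2, idx[3]] <- 1; L[2, idx[4]] <- -1
  est <- drop(L %*% fit$free)
  Vc <- L %*% vcov %*% t(L)
  stat <- drop(crossprod(est, solve(Vc, est)))
  list(statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, 2L, lower.tail = FALSE))
}

#' @export
print.ml_fit <- function(x, digits = 4, ...) {
  cat("Maximum-likelihood fit (", x$error, " error",
      if (any(x$equal_sigma)) paste0("; equal sigma2_",
        paste(names(x$equal_sigma)[x$equal_sigma], collapse = ",")),
      "): ", x$npar, " free parameters\n", sep = "")
  se <- rep(NA_real_, length(x$free))
  if (!is.null(x$vcov_model)) se <- sqrt(pmax(diag(x$vcov_model), 0))
  tab <- data.frame(estimate = unname(x$free), se = se,
                    row.names = x$free_names)
  print(round(tab, digits))
  cat(sprintf("effect muT2 - muT1 = %s (SE %s)\n",
              format(x$effect, digits = digits),
              format(x$effect_se, digits = digits)))
  cat("loglik =", format(x$loglik, digits = 10),
      if (!x$converged) " [NOT CONVERGED]",
      if (x$boundary) " [variance at boundary]", "\n")
  invisible(x)
}

# Flat key-value view of an ML fit for reports.
ml_fit_report <- function(x) {
  out <- as.list(x$free)
  names(out) <- x$free_names
  c(list(method = "ml", error = x$error,
         effect = x$effect, effect_se = x$effect_se,
         loglik = x$loglik, converged = x$converged),
    out)
}
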