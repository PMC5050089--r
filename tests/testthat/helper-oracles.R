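# Brute-force oracles, written independently of the package internals:
# every moment is recomputed with explicit sums so the estimators in R/ can
# be checked against first principles.

o_mean <- function(x) sum(x) / length(x)

o_cov <- function(x, y) {
  mx <- o_mean(x); my <- o_mean(y)
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - mx) * (y[i] - my)
  s / (length(x) - 1)
}

o_var <- function(x) o_cov(x, x)

# All method-of-moments point estimates, from scratch.
oracle_mom <- function(d, error) {
  g1 <- d$group == 1; g2 <- d$group == 2
  s1 <- g1 & d$in_substudy; s2 <- g2 & d$in_substudy
  mbar <- (d$m[, 1] + d$m[, 2]) / 2
  qb1 <- o_mean(d$q[g1]); qb2 <- o_mean(d$q[g2])
  qs1 <- o_mean(d$q[s1]); qs2 <- o_mean(d$q[s2])
  Mb1 <- o_mean(mbar[s1]); Mb2 <- o_mean(mbar[s2])
  theta_bio <- Mb2 - Mb1
  var_bio <- o_var(mbar[s1]) / sum(s1) + o_var(mbar[s2]) / sum(s2)
  if (error == "differential") {
    cQM <- c(o_cov(d$q[s1], mbar[s1]), o_cov(d$q[s2], mbar[s2]))
    cMM <- c(o_cov(d$m[s1, 1], d$m[s1, 2]), o_cov(d$m[s2, 1], d$m[s2, 2]))
    a1 <- cQM / cMM
    a0 <- c(qs1 - a1[1] * Mb1, qs2 - a1[2] * Mb2)
    theta_sr <- (qb2 - qs2) / a1[2] - (qb1 - qs1) / a1[1] + Mb2 - Mb1
    s2M <- c((o_var(d$m[s1, 1]) + o_var(d$m[s1, 2])) / 2 - cMM[1],
             (o_var(d$m[s2, 1]) + o_var(d$m[s2, 2])) / 2 - cMM[2])
    s2Q <- c(o_var(d$q[g1]) - a1[1]^2 * cMM[1],
             o_var(d$q[g2]) - a1[2]^2 * cMM[2])
  } else {
    s <- d$in_substudy
    cQM <- o_cov(d$q[s], mbar[s])
    cMM <- o_cov(d$m[s, 1], d$m[s, 2])
    a1 <- cQM / cMM
    a0 <- o_mean(d$q[s]) - a1 * o_mean(mbar[s])
    theta_sr <- (qb2 - qb1) / a1
    s2M <- (o_var(d$m[s, 1]) + o_var(d$m[s, 2])) / 2 - cMM
    s2Q <- o_var(d$q[s]) - a1^2 * cMM
  }
  list(theta_bio = theta_bio, var_bio = var_bio, theta_sr = theta_sr,
       alpha0 = a0, alpha1 = a1, sigma2_M = s2M, sigma2_Q = s2Q)
}

# Stratified nonparametric bootstrap of the MoM estimators: resample
# individuals within each group with replacement (sub-study membership
# travels with the individual).
bootstrap_mom <- function(d, error, n_boot, seed) {
  set.seed(seed)
  idx1 <- which(d$group == 1); idx2 <- which(d$group == 2)
  out <- matrix(NA_real_, n_boot, 3,
                dimnames = list(NULL, c("bio", "sr", "comb")))
  b <- 1
  while (b <= n_boot) {
    take <- c(sample(idx1, replace = TRUE), sample(idx2, replace = TRUE))
    db <- trial_dataset(d$group[take], d$q[take], d$m[take, , drop = FALSE])
    fit <- tryCatch(mom_fit(db, error), error = function(e) NULL)
    if (is.null(fit)) next
    out[b, ] <- c(fit$theta_bio, fit$theta_sr, fit$theta_combined)
    b <- b + 1
  }
  out
}

# A tiny deterministic two-group dataset with both in- and out-of-substudy
# members; values chosen so all covariances are nondegenerate.
toy_dataset <- function() {
  trial_dataset(
    group = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2),
    q = c(4.8, 4.1, 4.5, 4.9, 4.2, 4.6, 3.6, 3.9, 3.3, 3.8, 3.5, 3.4),
    m = rbind(c(4.7, 4.5), c(4.0, 4.2), c(4.4, 4.6), c(4.9, 4.7),
              NA, NA,
              c(3.4, 3.6), c(3.8, 3.7), c(3.2, 3.1), c(3.7, 3.9),
              NA, NA))
}

# Noise-free dataset: M1 = M2 = T, Q = a0 + a1 * T within each group.
noise_free_dataset <- function(a0 = c(2, 1), a1 = c(0.5, 0.8),
                               t1 = c(1, 2, 3, 4), t2 = c(2, 4, 6, 8)) {
  tt <- c(t1, t2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  trial_dataset(grp, a0[grp] + a1[grp] * tt, cbind(tt, tt))
}
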