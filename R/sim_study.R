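# Monte-Carlo evaluation: per-replicate estimates for each analysis
# method, and scenario-level operating characteristics (bias, MSE,
# empirical SD, mean model-based SE, 95% coverage, efficiency relative to
# the gold standard with biomarkers on 100% of individuals).

sim_methods_all <- c("bio", "mom_differential", "mom_nondifferential",
                     "ml_bio", "ml_differential", "ml_nondifferential")

# Biomarker-only estimate on a fully observed copy of the replicate: the
# gold standard against which efficiency is measured.
gold_estimate <- function(d) {
  full <- new_trial_dataset(d$group, d$q, attr(d, "m_full"))
  est <- estimate_theta_bio(full)
  c(estimate = est$estimate, se = sqrt(est$variance))
}

#' Run one simulation replicate
#'
#' Generates one trial from `cfg`, masks it to its calibration fraction,
#' and computes the requested intervention-effect estimates: biomarkers
#' only (`"bio"`), the combined method-of-moments estimator under the
#' differential and non-differential assumptions (`"mom_differential"`,
#' `"mom_nondifferential"`), and the corresponding maximum-likelihood
#' estimates (`"ml_bio"`, `"ml_differential"`, `"ml_nondifferential"`).
#' The gold-standard estimate (biomarker estimator on the unmasked
#' replicate) is always included as method `"gold"`.
#'
#' Invalid fits (degenerate moment estimates, non-converged likelihoods)
#' are flagged, never thrown.
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed for this replicate.
#' @param methods subset of
#'   `c("bio", "mom_differential", "mom_nondifferential", "ml_bio",
#'   "ml_differential", "ml_nondifferential")`.
#' @return Data frame with columns `method`, `estimate`, `se`, `valid`.
#' @export
run_replicate <- function(cfg, seed = NULL,
                          methods = c("bio", "mom_differential",
                                      "mom_nondifferential")) {
  methods <- match.arg(methods, sim_methods_all, several.ok = TRUE)
  d <- simulate_trial(cfg, seed = seed)
  gold <- gold_estimate(d)
  rows <- list(data.frame(method = "gold", estimate = gold[["estimate"]],
                          se = gold[["se"]], valid = TRUE))
  for (meth in methods) {
    row <- switch(meth,
      bio = {
        est <- estimate_theta_bio(d)
        data.frame(method = meth, estimate = est$estimate,
                   se = sqrt(est$variance), valid = TRUE)
      },
      mom_differential = ,
      mom_nondifferential = {
        err <- sub("^mom_", "", meth)
        fit <- mom_fit(d, err)
        data.frame(method = meth, estimate = fit$theta_combined,
                   se = if (is.na(fit$se_combined)) NA_real_
                        else fit$se_combined,
                   valid = fit$valid)
      },
      ml_bio = {
        # normal-theory MLE of the two sub-study means of Mbar
        mm <- mom_moments(d)$group
        v <- sum(vapply(mm, function(g)
          mean((g$mbar - g$Mbar)^2) / g$n, numeric(1)))
        data.frame(method = meth, estimate = mm[[2]]$Mbar - mm[[1]]$Mbar,
                   se = sqrt(v), valid = TRUE)
      },
      ml_differential = ,
      ml_nondifferential = {
        err <- sub("^ml_", "", meth)
        fit <- tryCatch(ml_fit(d, err), error = function(e) NULL)
        if (is.null(fit)) {
          data.frame(method = meth, estimate = NA_real_, se = NA_real_,
                     valid = FALSE)
        } else {
          data.frame(method = meth, estimate = fit$effect,
                     se = fit$effect_se,
                     valid = fit$converged && !fit$boundary)
        }
      })
    rows <- c(rows, list(row))
  }
  do.call(rbind, rows)
}

#' Summarize a scenario's replicates into operating characteristics
#'
#' For each method, over its valid replicates only: bias
#' (`mean(estimate) - true_effect`), MSE, empirical SD of the estimates,
#' model SE (square root of the mean model-based variance), coverage of the
#' nominal 95% normal-quantile confidence intervals
#' (`estimate +/- 1.96 se`, in percent), and efficiency
#' (`100 * var(gold-standard estimates) / var(method estimates)`, the
#' gold-standard variance taken over the same replicate subset).
#'
#' @param reps data frame of stacked [run_replicate()] results with a `rep`
#'   column identifying the replicate.
#' @param true_effect the generator's true intervention effect.
#' @return Data frame with one row per method: `method`, `bias`, `mse`,
#'   `emp_sd`, `model_se`, `coverage`, `efficiency`, `n_valid`.
#' @export
summarize_scenario <- function(reps, true_effect) {
  stopifnot(all(c("rep", "method", "estimate", "se", "valid") %in%
                  names(reps)))
  gold <- reps[reps$method == "gold", ]
  gold_by_rep <- stats::setNames(gold$estimate, gold$rep)
  out <- lapply(setdiff(unique(reps$method), "gold"), function(meth) {
    r <- reps[reps$method == meth & reps$valid & !is.na(reps$se), ]
    if (nrow(r) < 2L)
      stop("fewer than 2 valid replicates for method ", meth)
    est <- r$estimate
    g <- gold_by_rep[as.character(r$rep)]
    data.frame(method = meth,
               bias = mean(est) - true_effect,
               mse = mean((est - true_effect)^2),
               emp_sd = stats::sd(est),
               model_se = sqrt(mean(r$se^2)),
               coverage = 100 * mean(abs(est - true_effect) <=
                                       qnorm(0.975) * r$se),
               efficiency = 100 * stats::var(g) / stats::var(est),
               n_valid = nrow(r))
  })
  gold_all <- gold[gold$valid, ]
  out <- c(list(data.frame(method = "gold",
                           bias = mean(gold_all$estimate) - true_effect,
                           mse = mean((gold_all$estimate - true_effect)^2),
                           emp_sd = stats::sd(gold_all$estimate),
                           model_se = sqrt(mean(gold_all$se^2)),
                           coverage = 100 * mean(
                             abs(gold_all$estimate - true_effect) <=
                               qnorm(0.975) * gold_all$se),
                           efficiency = 100,
                           n_valid = nrow(gold_all))),
           out)
  do.call(rbind, out)
}

#' Run a full simulation scenario
#'
#' Generates `n_reps` independent replicates of `cfg` (each from its own
#' deterministic sub-seed of `seed`, so individual replicates are
#' reproducible), estimates the intervention effect by each requested
#' method, and summarizes the operating characteristics.
#'
#' @param cfg a [scenario_config()].
#' @param n_reps number of Monte-Carlo replicates; defaults to
#'   `cfg$n_reps`.
#' @param seed master seed; defaults to `cfg$seed`.
#' @param methods passed to [run_replicate()].
#' @return List of class `scenario_result` with `metrics` (the
#'   [summarize_scenario()] table), `replicates` (the per-replicate
#'   estimates) and `cfg`.
#' @export
run_scenario <- function(cfg, n_reps = cfg$n_reps, seed = cfg$seed,
                         methods = c("bio", "mom_differential",
                                     "mom_nondifferential")) {
  if (is.null(seed)) stop("a master seed is required")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  reps <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    out <- run_replicate(cfg, seed = rep_seeds[r], methods = methods)
    out$rep <- r
    out
  }))
  structure(list(metrics = summarize_scenario(reps, cfg$muT[2] - cfg$muT[1]),
                 replicates = reps, cfg = cfg, seed = seed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, digits = 3, ...) {
  cat("Scenario result (", x$cfg$error_structure, " error, sigma2_Q = ",
      x$cfg$sigma2_Q[1], ", calibration ",
      round(100 * x$cfg$calib_fraction), "%, ",
      max(x$replicates$rep), " replicates)\n", sep = "")
  m <- x$metrics
  m[2:7] <- lapply(m[2:7], round, digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Run a grid of simulation scenarios
#'
#' Crosses generator error structures, self-report error variances and
#' calibration fractions, running [run_scenario()] in each cell.  Each cell
#' gets its own deterministic sub-seed of `seed`.
#'
#' @param error_structure generator structures to cross.
#' @param sigma2_Q self-report error variances to cross.
#' @param calib_fraction calibration fractions to cross.
#' @param n_reps replicates per cell.
#' @param seed master seed.
#' @param methods passed to [run_replicate()].
#' @param ... further arguments to [scenario_config()] shared by all cells.
#' @return Long-format data frame: one row per (cell, method) with the
#'   scenario keys and the [summarize_scenario()] metrics.
#' @export
run_grid <- function(error_structure = c("differential", "nondifferential"),
                     sigma2_Q = c(0.09, 0.3, 0.5, 0.7),
                     calib_fraction = c(0.10, 0.25, 0.50, 1.00),
                     n_reps = 1000, seed = 1,
                     methods = c("bio", "mom_differential",
                                 "mom_nondifferential"),
                     ...) {
  cells <- expand.grid(error_structure = error_structure,
                       sigma2_Q = sigma2_Q,
                       calib_fraction = calib_fraction,
                       stringsAsFactors = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  out <- lapply(seq_len(nrow(cells)), function(k) {
    cfg <- scenario_config(cells$error_structure[k],
                           sigma2_Q = cells$sigma2_Q[k],
                           calib_fraction = cells$calib_fraction[k],
                           n_reps = n_reps, ...)
    res <- run_scenario(cfg, n_reps = n_reps, seed = cell_seeds[k],
                        methods = methods)
    cbind(cells[rep(k, nrow(res$metrics)), , drop = FALSE], res$metrics,
          row.names = NULL)
  })
  do.call(rbind, out)
}

#' Format a metrics table as fixed-width text
#'
#' @param grid a [run_grid()] (or single-scenario metrics) data frame.
#' @return Character vector of lines.
#' @export
format_metrics_table <- function(grid) {
  g <- grid
  num <- intersect(c("bias", "mse", "emp_sd", "model_se"), names(g))
  g[num] <- lapply(g[num], function(x) sprintf("%.3f", x))
  pct <- intersect(c("coverage", "efficiency"), names(g))
  g[pct] <- lapply(g[pct], function(x) sprintf("%.1f", x))
  utils::capture.output(print(g, row.names = FALSE))
}
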