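---
title: "Estimating intervention effects on an outcome measured with error:
  models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intervention effects on an outcome measured with error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietcalib)
```

## The problem

In a two-arm dietary intervention trial the quantity of interest is the
difference in expected true intake between the intervention and control
arms, $\theta = \mu_{T2} - \mu_{T1}$.  True intake $T_{ij}$ of individual
$j$ in arm $i$ is never observed.  Two kinds of surrogate are available:

* a **self-report** $Q_{ij}$ (e.g. a 24-h recall) on every participant,
  modelled as linear in true intake with additive error,
  $Q_{ij} = \alpha_{0i} + \alpha_{1i} T_{ij} + \epsilon_{Qij}$,
  $\mathrm{var}(\epsilon_{Qij}) = \sigma^2_{Qi}$.  Self-report is biased
  unless $\alpha_{0i} = 0,\ \alpha_{1i} = 1$, and the bias may be
  **differential**: participants coached to change their diet may also
  change how they report it, so $(\alpha_{0i}, \alpha_{1i})$ may depend on
  the arm.  The **non-differential** special case ties
  $\alpha_{01}=\alpha_{02}$ and $\alpha_{11}=\alpha_{12}$;
* a **recovery biomarker** (e.g. 24-h urinary sodium), unbiased for intake
  under the classical error model
  $M_{ijk} = T_{ij} + \epsilon_{Mijk}$,
  $\mathrm{var}(\epsilon_{Mijk}) = \sigma^2_{Mi}$, but measured with
  $K \ge 2$ replicates only in a **calibration sub-study** of $n_i \le N_i$
  participants per arm.

True intake itself is modelled as $T_{ij} = \mu_{Ti} + \epsilon_{Tij}$
with $\mathrm{var}(\epsilon_{Tij}) = \sigma^2_{Ti}$.  All error terms are
taken independent; on dietary data this is usually made tenable by a power
transform (see below).  The package estimates $\theta$ from the combined
data, by method of moments (`mom_fit()`) and by maximum likelihood
(`ml_fit()`), and evaluates the designs by simulation (`run_grid()`).

## Preprocessing

Dietary measurements are right-skewed; `power_transform(x, lam)` applies
`x^lam` with a user-supplied exponent (0.3 is a common Box-Cox choice for
urinary sodium; the package deliberately does not automate the Box-Cox
selection, since the exponent is a modelling decision that should be fixed
before estimation).  A recovery biomarker that captures a known mean
fraction of intake (86% for urinary sodium) is rescaled by
`scale_biomarker(m, fraction)`.  `preprocess_trial()` applies the rescaling
first and the power transform second, so the error models are posited for
the excretion-corrected biomarker on the transformed scale; the two
functions can be called directly in the other order if wanted.

## Method-of-moments estimation

Write $\bar M_{ij}$ for the mean of individual $j$'s two replicates (the
moment path uses the first two replicate columns; additional replicates are
carried by the container but not used — a documented limitation), $\bar
M_i$, $\bar Q_{is}$ for sub-study means and $\bar Q_i$ for the full-sample
self-report mean in arm $i$.  Two estimators of $\theta$:

1. **Biomarkers only**: $\hat\theta_{\mathrm{bio}} = \bar M_2 - \bar M_1$,
   unbiased under the classical error model regardless of the self-report
   error structure, with variance estimated by the sample variance of the
   per-individual means over each sub-study divided by $n_i$.
2. **Self-report based**: the slope of $Q$ on $T$ is identified from the
   sub-study because $\widehat{\mathrm{cov}}(M_1, M_2)$ estimates
   $\sigma^2_T$ free of biomarker error:
   $\hat\alpha_{1i} = \widehat{\mathrm{cov}}(Q, \bar M) /
   \widehat{\mathrm{cov}}(M_1, M_2)$, and
   $\hat\alpha_{0i} = \bar Q_{is} - \hat\alpha_{1i}\bar M_i$.  Under
   differential error,
   $\hat\theta_{\mathrm{sr}} = (\bar Q_2 - \bar Q_{2s})/\hat\alpha_{12} -
   (\bar Q_1 - \bar Q_{1s})/\hat\alpha_{11} + \bar M_2 - \bar M_1$; under
   non-differential error the covariances are pooled over both arms and
   $\hat\theta_{\mathrm{sr}} = (\bar Q_2 - \bar Q_1)/\hat\alpha_1$, which
   uses every participant's self-report and therefore genuinely adds
   information.

The two estimators are combined with the inverse-variance weights that
minimize the variance of the combination given their $2\times 2$ variance
matrix; weights are *not* clipped to $[0,1]$, because with a large
covariance the optimum can legitimately fall outside the unit interval.
At 100% calibration the differential-error $\hat\theta_{\mathrm{sr}}$
coincides with $\hat\theta_{\mathrm{bio}}$ and the combination degenerates;
`combine_estimates()` detects this and returns the biomarker estimator.

### Variance of the two estimators

The variance matrix of
$(\hat\theta_{\mathrm{bio}}, \hat\theta_{\mathrm{sr}})$ is obtained from
stacked estimating equations: one mean-zero equation per moment parameter
(the full-sample self-report mean, the sub-study self-report and biomarker
means, $\mathrm{cov}(Q,\bar M)$ and $\mathrm{cov}(M_1,M_2)$ — per arm
under differential error, pooled under non-differential error, where the
pooled equations also carry the two arm-specific full-sample means and
sub-study biomarker means).  At the solution with $n$-denominator moments,
the averaged-derivative matrix $A$ of this system is diagonal, so the
sandwich $A^{-1} B A^{-\top}/N$ with the empirical score covariance $B$ is
available in closed form; the delta method then maps it through the two
estimator formulas.  A small-sample factor $n_i/(n_i-1)$ per arm (pooled
$n/(n-1)$ under non-differential error) makes the biomarker-arm entry equal
the familiar $n-1$-denominator variance formula exactly.  The test suite
validates the whole construction against a 2000-resample stratified
bootstrap.

Two conventions worth stating explicitly: sample covariances use the
$n-1$ denominator throughout; and the self-report error variance
$\hat\sigma^2_{Qi} = \widehat{\mathrm{var}}(Q) - \hat\alpha_{1i}^2
\widehat{\mathrm{cov}}(M_1,M_2)$ takes $\widehat{\mathrm{var}}(Q)$ over the
arm's full sample under differential error but over the pooled sub-study
under non-differential error, so that the between-arm mean component
inflates both terms consistently.  The biomarker error variance uses the
average of the two per-replicate sample variances, which makes the
estimate exactly zero for error-free replicates.

### Validity flags

A fit is flagged invalid — never silently repaired — when any moment it
relies on is degenerate: $\widehat{\mathrm{cov}}(M_1,M_2) \le 0$ (the slope
denominator), a negative error-variance estimate, or a
non-positive-definite estimator variance matrix.  With a small sub-study
and a small $\sigma^2_Q$ these events are not rare (a few percent of
replicates at 10% calibration), because $\hat\sigma^2_Q$ involves
$\widehat{\mathrm{cov}}(Q,\bar M)^2/\widehat{\mathrm{cov}}(M_1,M_2)$, whose
right tail is heavy when the replicate covariance is imprecise.  Simulation
drivers drop invalid replicates per method and report `n_valid`.

## Maximum likelihood

Sub-study members contribute a trivariate normal likelihood for
$(M_1, M_2, Q)$ with mean $(\mu_{Ti}, \mu_{Ti},
\alpha_{0i}+\alpha_{1i}\mu_{Ti})$ and the covariance implied by the three
error models (`implied_moments()`); the remaining participants contribute
a univariate normal for $Q$.  Arms are independent, so the joint
six-variate formulation factorizes into the per-arm blocks implemented
here.  Constraint options tie the $\alpha$'s (non-differential) and any of
the three variances across arms; assumptions are testable by likelihood
ratio (`lrt()`) or Wald (`wald_differential()`) tests — the comparison of
differential against non-differential error has 2 degrees of freedom.
Both tests are exposed and neither is privileged.

Numerical choices: the likelihood depends on the data only through
per-arm sufficient statistics, so evaluations are O(1) after one pass; the
mean parameters are linear in the model and are profiled out exactly by
generalized least squares inside the objective; the remaining variance
parameters are optimized on the log scale with a floor of $10^{-10}$
(L-BFGS-B, `factr = 1e5`, at most 500 iterations), which keeps the
likelihood bounded on degenerate noise-free data — there the profiled
means reproduce the arm sample means exactly and the fit is flagged
`boundary`.  Starting values come from the method-of-moments fit when it
is valid, otherwise from naive moments with slope 1.  Model-based standard
errors invert a numerical observed-information matrix computed in the
natural parameterization; non-convergence and boundary solutions are
surfaced as flags, never silently accepted.

Because the estimators depend on the data only through first and second
moments, the point estimates remain consistent when the data are not
multivariate normal, but the model-based variances need not be valid;
`sandwich_vcov()` provides the robust alternative
$A^{-1} B A^{-\top}$ with $A$ the averaged negative Hessian and $B$ the
empirical covariance of per-individual scores.  Bootstrap variances are
not implemented (only the sandwich and model-based forms).

## The trial generator

`simulate_trial()` draws, per arm, true intakes
$T \sim N(\mu_{Ti}, \sigma^2_{Ti})$, one self-report and two biomarker
replicates from the three error models, then masks both replicates outside
a random calibration sub-study.  Defaults are the package's reference
operating conditions: 500 per arm, $\mu_T = (4.6, 4.1)$ (effect $-0.5$),
$\sigma^2_T = 0.1$, $\sigma^2_M = 0.2$ (biomarker two-replicate-mean
reliability 0.5), $\sigma^2_Q = 0.09$, calibration fraction 0.10, and the
differential coefficients $\alpha_0 = (0.3, 1.5)$,
$\alpha_1 = (0.8, 0.5)$ or the shared non-differential pair
$(0.9, 0.65)$.

Masking is stratified by arm, keeping exactly
`round(fraction * n_per_group)` members, so the per-arm sub-study size is
fixed by design rather than random — matching how calibration percentages
are reported.  One master seed per scenario deterministically derives one
sub-seed per replicate, so any single replicate can be regenerated
bitwise.

A non-normal option draws $T$ from a gamma distribution shifted and
scaled to the target mean and variance, with skewness as the free shape
control ($k = 4/\gamma^2$); skewness 0 falls back to the normal draw.  The
gamma family is a configurable stand-in — it emulates the right skew of
intake distributions, not any particular measured population.  The
generator emulates independent, homoscedastic errors and a single
measurement occasion; real dietary data can violate all three (intake-
dependent reporting error, correlated within-person errors, repeated
visits), so passing simulation checks demonstrates correctness of the
estimators under the stated models, not robustness to those violations.

## Simulation studies

`run_replicate()` computes, per simulated trial: the gold-standard
estimate (biomarker estimator on the unmasked copy), the biomarkers-only
estimate on the masked data, and the combined estimate under each error
assumption (method of moments by default; maximum likelihood optionally).
`summarize_scenario()` reports bias, MSE, empirical SD, the square root of
the mean model-based variance, coverage of nominal 95% normal-quantile
intervals ($\pm 1.96\,\mathrm{SE}$ — the interval construction is a
package convention), and efficiency
$100 \cdot \mathrm{var}(\text{gold})/\mathrm{var}(\text{method})$ with the
gold variance taken over the same valid-replicate subset.  Reusing the
unmasked copy of each replicate for the gold standard (common random
numbers) reduces Monte-Carlo noise in the efficiency ratios and keeps the
whole grid deterministic.

Problem sizes used by the shipped checks: operating-characteristic cells
run 1000 replicates of the 1000-person design; the likelihood
parameter-recovery study runs 1000 replicates at 8000 per arm, a size at
which the $O(1/n)$ finite-sample bias of the nonlinear parameters is
comfortably below Monte-Carlo resolution; bootstrap validation uses one
1500-per-arm dataset with 2000 resamples.

## Known limitations

* The moment path assumes exactly two usable biomarker replicates per
  sub-study member; unbalanced replicate counts are not supported.
* With a 10% calibration sub-study the sampling distributions of the
  slope ratio and of the self-report-based estimator are heavy-tailed;
  combined-estimator efficiencies measured over all valid replicates are
  accordingly sensitive to the tails, and per-replicate weight estimation
  itself costs efficiency relative to oracle weights.
* Two arms only; longitudinal designs and change-from-baseline outcomes
  are out of scope.
* The cost/sample-size trade-off between enrolling self-report-only and
  biomarker-plus-self-report participants is discussed in the README but
  not implemented as a calculator.
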