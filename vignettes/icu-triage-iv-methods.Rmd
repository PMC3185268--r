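---
title: "Methods: instrumental variables and propensity matching for ICU triage cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrumental variables and propensity matching for ICU triage cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whether admission to an intensive care unit (ICU) reduces in-hospital
mortality cannot be settled by a randomised trial: triage decisions are made
for sick people under time pressure. Observational triage cohorts are the
only evidence, and they are confounded twice over — by the measured severity
scores a physician sees (age, SOFA, SAPS II, GCS, Karnofsky performance
status) and by everything the physician sees that is never recorded.
Covariate adjustment and propensity-score matching handle only the first
kind. Instrumental-variable (IV) analysis targets both, at the price of a
strong, untestable assumption and much lower precision.

`ivtriage` implements the full comparison on one cohort: crude and adjusted
regression, propensity-score caliper matching, diagnostics for choosing an
instrument, and five IV estimators with bootstrap inference, together with a
synthetic cohort generator whose causal structure is known exactly, so every
claim the pipeline makes can be tested against ground truth.

## Notation and causal model

Let $Y$ be in-hospital death (1/0), $X$ ICU admission (1/0), $W$ the vector
of measured baseline covariates, $U$ an unmeasured confounder and $Z$ a
candidate instrument. An instrument must (1) affect the outcome only through
treatment (the *exclusion restriction*), (2) predict treatment (*strength*),
and (3) be unrelated to patient characteristics, measured or not.

The synthetic generator (`sim_config()` / `simulate_cohort()`) encodes this
structure directly:

$$P(X = 1) = \operatorname{logit}^{-1}(\gamma_0 + \gamma_Z Z + \gamma_W' W + \gamma_U U), \qquad U \sim N(0, \sigma_U^2),$$

with the outcome either logistic,
$P(Y=1) = \operatorname{logit}^{-1}(\alpha_0 + \beta_X X + \alpha_W' W + \alpha_U U)$,
or linear-probability,
$P(Y=1) = \alpha_0 + \beta_X X + \alpha_W' W + \alpha_U U$.
$Z$ never enters the outcome model or the covariate draws, so the exclusion
restriction holds by construction. A single latent Gaussian $U$ is the
minimal structure that produces unmeasured confounding; real cohorts
presumably hide several correlated confounders, and nothing here emulates
effect modification by $U$, informative missingness, or repeated triage of
the same patient. Passing recovery tests on these cohorts therefore shows
the estimators do what their theory promises under their assumptions — not
that those assumptions hold in any particular hospital system.

Both outcome kinds exist because the estimators target different scales: the
linear-probability model makes the true risk difference (RD) exactly
$\beta_X$, the natural truth for two-stage least squares, while the logistic
model makes $\beta_X$ an exact conditional log odds ratio (OR). Under the
linear-probability model, event probabilities are clamped to $[0,1]$ at draw
time; a configuration is *rejected* (not silently clamped) unless at least
99% of pre-clamp probabilities lie in $[0.01, 0.99]$, because heavy clamping
would quietly bend the structural risk difference away from $\beta_X$.

`eldicus_sim_config()` freezes an "ELDICUS-like" default: 8,201 patients of
whom about 82.3% are admitted, five severity covariates with realistic
moments (age ≈ 59.6 ± 18.3 years, SOFA ≈ 4.8 ± 2.9, SAPS II ≈ 30 ± 16,
GCS ≈ 12.5 ± 4.3, Karnofsky ≈ 79 ± 20), a binary physician-specialty
instrument with prevalence 0.5 and a log-odds effect of 0.8 on admission
(univariate OR ≈ 2.2), seven country-like clusters, and a *true null*
treatment effect. The covariate coefficients were calibrated once so that
functionally fitter patients are admitted more and die less (crude OR ≈
0.86, protective) while the latent confounder pushes the adjusted estimate
the other way (adjusted OR ≈ 1.23, harmful) — the signature pattern of a
triage cohort in which only instrumented analyses recover the null.
Marginal mortality is calibrated to ≈ 25%. Cluster labels are assigned
uniformly at random and carry no effect; they exist to exercise the cluster
bootstrap.

## The estimators

**Crude and adjusted regression** (`crude_and_adjusted()`). Logistic
regression of $Y$ on $X$ (± covariates) for the OR; difference in arm
proportions and a linear probability model for the RD. The RD sign
convention is *admitted minus refused* throughout the package.

**Propensity-score matching** (`fit_propensity()`,
`match_without_replacement()`, `matched_effect()`). The propensity score is
a logistic model of admission on covariates. Matching is 1:1, greedy
nearest-neighbour on the logit scale, without replacement, with a caliper of
0.2 times the sample SD of the logit propensity score. The estimand is the
effect among patients similar to those who could be matched — essentially
the treated who resemble refusals (ATT among the matchable).

**Instrument diagnostics** (`first_stage_strength()`,
`instrument_treatment_or()`, `balance_table()`, `evaluate_instruments()`).
Strength is the partial F-statistic of $Z$ in a linear first stage of the
0/1 treatment on $Z$ and covariates (equal to the squared t-statistic for a
single instrument), with partial $r^2 = t^2/(t^2 + \text{df})$; F < 10 flags
a weak instrument. Because a binary treatment sits awkwardly in a linear
first stage, the univariate odds ratio of $Z$ on $X$ is reported alongside.
Validity is probed by comparing covariate balance stratified by $Z$ with
balance stratified by $X$: a good instrument behaves like randomisation, so
its strata should be nearly balanced.

**Five IV estimators** (RD scale: `wald_estimator()`,
`two_stage_least_squares()`, `three_stage_ls()`; OR scale:
`two_stage_logistic()`, `two_stage_probit()`):

$$\hat\beta_{IV} = \frac{\hat E[Y \mid Z=1] - \hat E[Y \mid Z=0]}
                        {\hat E[X \mid Z=1] - \hat E[X \mid Z=0]}$$

is the Wald ratio. 2SLS replaces $X$ in the outcome regression with its
first-stage OLS prediction; the two-stage logistic (2LR) and two-stage
probit use logistic/probit stages instead, with probit coefficients
multiplied by 1.6 (the standard probit→logistic mapping) before
exponentiation. The three-stage variant first converts $Z$ into a predicted
admission probability by logistic regression and then feeds that probability
to 2SLS as the instrument. With one binary $Z$ and no covariates, Wald, 2SLS
and 3LS coincide exactly (the predicted probability is a monotone two-valued
recoding of $Z$); this identity is asserted to $10^{-8}$ in the test suite.
All IV estimators estimate a *local* average effect — the effect among
patients whose admission the instrument actually shifts.

## Inference

Second-stage analytic standard errors are wrong for generated regressors, so
every IV interval comes from a percentile bootstrap (`bootstrap_ci()`):
patients (or whole clusters, when a cluster column is named) are resampled
with replacement, the estimator is re-run per replicate, and the 2.5/97.5
percentiles form the 95% interval. The reference analysis uses 1,000
iterations; the bundled demonstration script uses 500. The two-sided p-value
is the percentile-crossing construction with a +1 continuity correction,
$p = 2\min(\#\{\hat\beta \le \text{null}\}+1, \#\{\hat\beta \ge \text{null}\}+1)/(B_{ok}+1)$,
never below $2/(B+1)$ — bootstrap p-values are otherwise ambiguous, so the
package fixes one convention and documents it. Replicates
where the estimator fails (a zero Wald denominator in a resample, say) are
dropped and counted; if more than 20% fail, inference is refused rather than
reported from the surviving replicates.

## Numerical choices and edge cases

* Regression engine: least-squares, logistic and probit fits delegate to R's
  QR-based fitters; an intercept is always prepended; rank-deficient designs
  error naming the collinear columns; logistic/probit non-convergence is an
  error, and quasi-complete separation is detected as a standardised
  coefficient exceeding 15 in absolute value (a pragmatic threshold).
  First stages of the multi-stage estimators are prediction-only and skip
  the separation guard — a separated first stage still produces monotone
  fitted probabilities, and the `Z := X` reduction identities rely on this.
* Matching: minority arm matched into the majority arm (in a triage cohort
  the refused minority); processing order is seeded-random; distance ties
  break on the smallest patient id so runs reproduce across platforms;
  the caliper has a floor of $10^{-6}$ to survive degenerate, near-constant
  propensity scores. Optimal (non-greedy) matching is out of scope.
* Standardized differences use the pooled-SD formula
  $d = (\bar w_1 - \bar w_0)/\sqrt{(s_1^2 + s_0^2)/2}$ (proportion variant
  for binary covariates). When both groups have zero variance, $d$ is
  undefined and excluded from mean |d| summaries.
* Candidate ranking in `evaluate_instruments()` is deliberately explicit and
  lexicographic — non-weak first (F ≥ 10), then smallest mean |d| across
  instrument strata, then largest F — because "strong and balanced" blends
  criteria that can disagree; an explicit rule is reproducible.
* Group-rate dichotomization (`dichotomize_by_group_rate()`) uses a default
  threshold of 0.85 on admission rates, the convention for splitting a
  multi-country triage cohort into two roughly equal halves;
  `balanced_rate_threshold()` finds the most even cut empirically.
* RD estimates outside $[-1, 1]$ (possible for multi-stage estimators with
  weak instruments) are flagged `out_of_range`, never clipped.
* The two-stage probit uses the response-scale predicted probability as the
  stage-2 regressor, paralleling the 2LR construction, rather than the
  linear index; either choice is defensible and this one keeps the two
  estimators directly comparable.

## Problem sizes used in the validation studies

The test suite's simulation studies use sizes chosen to make Monte-Carlo
error small relative to the assertion margins: estimator-recovery runs use
200 replicates of n = 10,000 linear-probability cohorts (null effect,
confounder loadings $\gamma_U = \alpha_U = 1$ with $\sigma_U = 0.12$, a
measured confounder with coefficient 0.1 on the outcome, and a first-stage
F well above 100); bootstrap-coverage runs use 200 outer replicates of
n = 2,000 with B = 200; weak-instrument spread comparisons use 200
replicates of n = 5,000 on a $\gamma_Z$ grid of 0.8/0.4/0.2; balance and
matching properties use 50 replicates of n = 1,200. The analytic oracle for
the naive-OLS bias under the linear-probability model is
$\operatorname{cov}(X, \alpha_W' W + \alpha_U U)/\operatorname{var}(X)$,
evaluated on an independent draw of the structural components. The
$\sigma_U = 0.12$ choice keeps the linear-probability configuration valid
under the 99% clamping rule while loading the confounder coefficients at 1;
the measured covariate supplies the bulk of the naive-OLS bias, which the
latent path alone cannot reach under that validity constraint.

## Known limitations

* The generator draws covariates independently; real severity scores are
  correlated, which strengthens propensity models relative to this test bed.
* With instruments of realistic strength (partial $r^2$ in the 0.001–0.02
  range), single-cohort IV point estimates are extremely noisy; only their
  *average* behaviour over replicates, and their interval coverage, are
  meaningful quality measures, and that is what the tests assert.
* The matched-cohort logistic model treats matched patients as independent;
  a pair-aware (conditional) analysis is not implemented.
* Odds ratios are non-collapsible: marginal and conditional ORs differ even
  without confounding, which is why both OR and RD tables are always
  reported and why the OR-scale IV estimates should not be compared
  numerically to the adjusted conditional OR.
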