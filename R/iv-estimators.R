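#' Construct an effect-estimate row
#'
#' All estimators in the package return this one-row tibble so results
#' chain naturally into report tables. Risk-difference estimates outside
#' \[-1, 1\] are possible for the multi-stage estimators and are flagged via
#' `out_of_range`, never clipped; odds ratios must be positive.
#'
#' @param estimator One of `"crude"`, `"adjusted"`, `"ps_matched"`,
#'   `"wald"`, `"2sls"`, `"2lr"`, `"probit2"`, `"3ls"`.
#' @param scale `"OR"` or `"RD"`.
#' @param point Point estimate.
#' @param ci_low,ci_high Interval bounds (`NA` until inference is attached).
#' @param level Confidence level.
#' @param p_value P-value (`NA` until inference is attached).
#' @param n_used Observations used.
#' @param ci_method `"wald_analytic"`, `"bootstrap_percentile"` or `NA`.
#' @param weak_instrument Weak first-stage flag.
#' @return A one-row tibble of class `"effect_estimate"`.
#' @export
effect_estimate <- function(estimator, scale, point,
                            ci_low = NA_real_, ci_high = NA_real_,
                            level = 0.95, p_value = NA_real_,
                            n_used = NA_integer_, ci_method = NA_character_,
                            weak_instrument = FALSE) {
  scale <- match.arg(scale, c("OR", "RD"))
  estimator <- match.arg(estimator,
                         c("crude", "adjusted", "ps_matched", "wald",
                           "2sls", "2lr", "probit2", "3ls"))
  point <- as.numeric(point)
  if (!is.finite(point)) stop("non-finite point estimate", call. = FALSE)
  if (scale == "OR" && point <= 0) {
    stop("odds-ratio estimates must be positive", call. = FALSE)
  }
  if (!is.na(ci_low) && !is.na(ci_high) && ci_low > ci_high) {
    stop("ci_low must not exceed ci_high", call. = FALSE)
  }
  out <- tibble::tibble(
    estimator = estimator,
    scale = scale,
    point = point,
    ci_low = as.numeric(ci_low),
    ci_high = as.numeric(ci_high),
    level = level,
    p_value = as.numeric(p_value),
    n_used = as.integer(n_used),
    ci_method = ci_method,
    weak_instrument = isTRUE(weak_instrument),
    out_of_range = scale == "RD" && abs(point) > 1
  )
  structure(out, class = c("effect_estimate", class(out)))
}

cohort_xy <- function(cohort) {
  check_columns(cohort, c("treatment", "outcome"))
  if (!all(cohort$treatment %in% c(0, 1)) || !all(cohort$outcome %in% c(0, 1))) {
    stop("treatment and outcome must be coded 0/1", call. = FALSE)
  }
  if (length(unique(cohort$treatment)) < 2) {
    stop("need both treated and untreated patients", call. = FALSE)
  }
  list(x = as.numeric(cohort$treatment), y = as.numeric(cohort$outcome))
}

design_of <- function(cohort, cols) {
  if (!length(cols)) {
    matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  } else {
    as.matrix(cohort[, cols, drop = FALSE])
  }
}

#' Wald (ratio) instrumental-variable estimator
#'
#' The classic IV estimator for a binary instrument: the between-stratum
#' difference in outcome means divided by the between-stratum difference in
#' treatment means,
#' \deqn{\hat\beta_{IV} = \frac{\hat E[Y\mid Z=1]-\hat E[Y\mid Z=0]}
#'                             {\hat E[X\mid Z=1]-\hat E[X\mid Z=0]},}
#' a risk difference per unit of instrument-induced treatment change.
#' Confidence intervals come from [bootstrap_ci()], not from an analytic
#' formula.
#'
#' @param cohort Cohort tibble.
#' @param z_name Binary instrument column.
#' @return A one-row `"effect_estimate"` (RD scale, point only).
#' @export
wald_estimator <- function(cohort, z_name) {
  xy <- cohort_xy(cohort)
  check_columns(cohort, z_name)
  z <- cohort[[z_name]]
  if (!all(z %in% c(0, 1)) || length(unique(z)) < 2) {
    stop("instrument '", z_name, "' must be binary with both strata non-empty",
         call. = FALSE)
  }
  dx <- mean(xy$x[z == 1]) - mean(xy$x[z == 0])
  if (abs(dx) < 1e-12) {
    stop("uninformative instrument: treatment rate identical in both instrument strata",
         call. = FALSE)
  }
  dy <- mean(xy$y[z == 1]) - mean(xy$y[z == 0])
  effect_estimate("wald", "RD", dy / dx, n_used = nrow(cohort))
}

first_stage_weak <- function(cohort, z_name, covariate_names) {
  fs <- first_stage_strength(cohort, z_name, covariate_names)
  if (fs$weak) {
    warning("weak instrument: first-stage partial F = ",
            signif(fs$partial_f, 4), " < 10", call. = FALSE)
  }
  fs$weak
}

#' Two-stage least squares
#'
#' Stage 1 regresses the 0/1 treatment on the instrument and covariates by
#' ordinary least squares; stage 2 regresses the outcome on the stage-1
#' fitted treatment and the same covariates. The coefficient on the fitted
#' treatment estimates the causal risk difference among patients whose
#' admission the instrument shifts. A weak first stage (partial F < 10)
#' attaches a warning and a flag, not an error.
#'
#' @param cohort Cohort tibble.
#' @param z_name Instrument column (binary or continuous).
#' @param covariate_names Covariates entering both stages.
#' @return A one-row `"effect_estimate"` (RD scale, point only).
#' @export
two_stage_least_squares <- function(cohort, z_name, covariate_names = character()) {
  xy <- cohort_xy(cohort)
  check_columns(cohort, c(z_name, covariate_names))
  W <- design_of(cohort, covariate_names)
  stage1 <- fit_linear(cbind(design_of(cohort, z_name), W), xy$x)
  xhat <- stage1$fitted_values
  if (sd(xhat) < 1e-10) {
    stop("uninformative instrument: first-stage fitted treatment is constant",
         call. = FALSE)
  }
  weak <- first_stage_weak(cohort, z_name, covariate_names)
  stage2 <- fit_linear(cbind(xhat = xhat, W), xy$y)
  effect_estimate("2sls", "RD", stage2$coefficients["xhat"],
                  n_used = nrow(cohort), weak_instrument = weak)
}

#' Two-stage logistic regression
#'
#' The two linear stages of 2SLS replaced by logistic regressions: stage 1
#' fits admission on instrument and covariates, stage 2 fits the outcome on
#' the stage-1 predicted admission probability and the same covariates. The
#' exponentiated coefficient on the predicted probability is reported as an
#' odds ratio.
#'
#' @inheritParams two_stage_least_squares
#' @return A one-row `"effect_estimate"` (OR scale, point only).
#' @export
two_stage_logistic <- function(cohort, z_name, covariate_names = character()) {
  xy <- cohort_xy(cohort)
  check_columns(cohort, c(z_name, covariate_names))
  W <- design_of(cohort, covariate_names)
  stage1 <- predict_logistic(cbind(design_of(cohort, z_name), W), xy$x)
  xhat <- stage1$fitted_values
  if (sd(xhat) < 1e-10) {
    stop("uninformative instrument: first-stage predicted treatment is constant",
         call. = FALSE)
  }
  weak <- first_stage_weak(cohort, z_name, covariate_names)
  stage2 <- fit_logistic(cbind(xhat = xhat, W), xy$y)
  effect_estimate("2lr", "OR", exp(stage2$coefficients["xhat"]),
                  n_used = nrow(cohort), weak_instrument = weak)
}

#' Two-stage probit with the 1.6 rescaling
#'
#' As [two_stage_logistic()] but with probit links in both stages; probit
#' coefficients are not log odds ratios, so the stage-2 coefficient on the
#' predicted admission probability is multiplied by 1.6 — the standard
#' approximation mapping probit to logistic coefficients — before
#' exponentiation to an odds ratio.
#'
#' @inheritParams two_stage_least_squares
#' @return A one-row `"effect_estimate"` (OR scale, point only).
#' @export
two_stage_probit <- function(cohort, z_name, covariate_names = character()) {
  xy <- cohort_xy(cohort)
  check_columns(cohort, c(z_name, covariate_names))
  W <- design_of(cohort, covariate_names)
  stage1 <- predict_probit(cbind(design_of(cohort, z_name), W), xy$x)
  xhat <- stage1$fitted_values
  if (sd(xhat) < 1e-10) {
    stop("uninformative instrument: first-stage predicted treatment is constant",
         call. = FALSE)
  }
  weak <- first_stage_weak(cohort, z_name, covariate_names)
  stage2 <- fit_probit(cbind(xhat = xhat, W), xy$y)
  effect_estimate("probit2", "OR", exp(1.6 * stage2$coefficients["xhat"]),
                  n_used = nrow(cohort), weak_instrument = weak)
}

#' Three-stage least squares
#'
#' A preliminary logistic regression of admission on the instrument and
#' covariates produces a predicted admission probability, which then plays
#' the role of the instrument in an ordinary two-stage least-squares run
#' (stages 1-2 unchanged). With a single binary instrument and no
#' covariates the predicted probability is a monotone two-valued recoding of
#' the instrument, so the estimator coincides with 2SLS and the Wald ratio.
#'
#' @inheritParams two_stage_least_squares
#' @return A one-row `"effect_estimate"` (RD scale, point only).
#' @export
three_stage_ls <- function(cohort, z_name, covariate_names = character()) {
  xy <- cohort_xy(cohort)
  check_columns(cohort, c(z_name, covariate_names))
  W <- design_of(cohort, covariate_names)
  stage0 <- predict_logistic(cbind(design_of(cohort, z_name), W), xy$x)
  phat <- stage0$fitted_values
  if (sd(phat) < 1e-10) {
    stop("uninformative instrument: preliminary predicted probability is constant",
         call. = FALSE)
  }
  aug <- dplyr::mutate(cohort, .phat = phat)
  est <- two_stage_least_squares(aug, ".phat", covariate_names)
  est$estimator <- "3ls"
  est
}
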