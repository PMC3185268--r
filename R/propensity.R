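#' Fit a propensity-score model
#'
#' Logistic regression of the admission decision on baseline covariates,
#' giving each patient's estimated probability of ICU admission. The
#' matching caliper is set to 0.2 times the sample standard deviation of the
#' logit of the propensity score (with a floor of 1e-6 so a degenerate,
#' near-constant score still yields a usable width).
#'
#' @param cohort Cohort tibble with a 0/1 `treatment` column.
#' @param covariate_names Covariates entering the propensity model.
#' @param caliper_multiplier Width multiplier on SD(logit PS); default 0.2.
#' @return A `"propensity_fit"`: list with `model` (a [fit_logistic()]
#'   result), `ps`, `logit_ps`, `caliper`, `covariate_names`.
#' @examples
#' co <- simulate_cohort(eldicus_sim_config(n_patients = 1000))
#' pf <- fit_propensity(co, c("age", "sofa", "gcs"))
#' glance(pf)
#' @export
fit_propensity <- function(cohort, covariate_names, caliper_multiplier = 0.2) {
  check_columns(cohort, c("treatment", covariate_names))
  X <- as.matrix(cohort[, covariate_names, drop = FALSE])
  model <- fit_logistic(X, as.numeric(cohort$treatment))
  ps <- model$fitted_values
  logit_ps <- qlogis(ps)
  caliper <- max(caliper_multiplier * sd(logit_ps), 1e-6)
  structure(
    list(model = model, ps = ps, logit_ps = logit_ps, caliper = caliper,
         covariate_names = covariate_names, patient_id = cohort$patient_id),
    class = "propensity_fit"
  )
}

#' @export
#' @method print propensity_fit
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> n =", x$model$n_obs,
      "| caliper =", signif(x$caliper, 5), "on the logit scale\n")
  invisible(x)
}

#' @export
#' @method tidy propensity_fit
tidy.propensity_fit <- function(x, ...) tidy(x$model)

#' @export
#' @method glance propensity_fit
glance.propensity_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$model$n_obs,
    n_covariates = length(x$covariate_names),
    caliper = x$caliper,
    sd_logit_ps = sd(x$logit_ps)
  )
}

#' Caliper matching without replacement
#'
#' Greedy 1:1 nearest-neighbour matching on the logit propensity score.
#' Patients in the minority arm (the refused arm, in a typical triage
#' cohort) are processed in a seeded random order; each is paired with the
#' closest not-yet-used majority-arm patient whose logit-PS distance is
#' within the caliper. Distance ties are broken by the smallest
#' `patient_id`, so a run is fully reproducible given the seed. No patient
#' is ever reused.
#'
#' @param fit A [fit_propensity()] result computed on `cohort`.
#' @param cohort The same cohort tibble.
#' @param seed Integer seed for the processing order.
#' @param caliper Override for the caliper width (defaults to `fit$caliper`).
#' @return A `"matched_cohort"`: list with `pairs` (tibble of
#'   `treated_id`, `control_id`, `distance`), `caliper_used`,
#'   `n_unmatched_treated`, `n_unmatched_control`.
#' @export
match_without_replacement <- function(fit, cohort, seed = 1L, caliper = NULL) {
  stopifnot(inherits(fit, "propensity_fit"))
  check_columns(cohort, c("patient_id", "treatment"))
  if (length(fit$logit_ps) != nrow(cohort) ||
      !identical(fit$patient_id, cohort$patient_id)) {
    stop("propensity fit was not computed on this cohort", call. = FALSE)
  }
  caliper <- caliper %||% fit$caliper
  trt <- cohort$treatment
  if (!any(trt == 1) || !any(trt == 0)) {
    stop("both treatment arms must be non-empty for matching", call. = FALSE)
  }
  minority <- if (sum(trt == 1) <= sum(trt == 0)) 1 else 0
  min_idx <- which(trt == minority)
  maj_idx <- which(trt == 1 - minority)
  order_min <- withr::with_seed(as.integer(seed), sample(min_idx))
  lp <- fit$logit_ps
  id <- cohort$patient_id
  used <- logical(length(trt))
  pair_min <- integer(0); pair_maj <- integer(0); pair_d <- numeric(0)
  for (i in order_min) {
    avail <- maj_idx[!used[maj_idx]]
    if (!length(avail)) break
    d <- abs(lp[avail] - lp[i])
    dmin <- min(d)
    if (dmin > caliper) next
    cand <- avail[d == dmin]
    j <- cand[which.min(id[cand])] # tie-break: smallest patient_id
    used[j] <- TRUE
    pair_min <- c(pair_min, i); pair_maj <- c(pair_maj, j); pair_d <- c(pair_d, dmin)
  }
  treated_idx <- if (minority == 1) pair_min else pair_maj
  control_idx <- if (minority == 1) pair_maj else pair_min
  pairs <- tibble::tibble(
    treated_id = id[treated_idx],
    control_id = id[control_idx],
    distance = pair_d
  )
  structure(
    list(
      pairs = pairs,
      caliper_used = caliper,
      n_unmatched_treated = sum(trt == 1) - nrow(pairs),
      n_unmatched_control = sum(trt == 0) - nrow(pairs)
    ),
    class = "matched_cohort"
  )
}

#' @export
#' @method print matched_cohort
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort>", nrow(x$pairs), "pairs | caliper",
      signif(x$caliper_used, 5), "| unmatched:", x$n_unmatched_treated,
      "treated,", x$n_unmatched_control, "control\n")
  invisible(x)
}

#' @export
#' @method tidy matched_cohort
tidy.matched_cohort <- function(x, ...) x$pairs

#' @export
#' @method glance matched_cohort
glance.matched_cohort <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    caliper_used = x$caliper_used,
    n_unmatched_treated = x$n_unmatched_treated,
    n_unmatched_control = x$n_unmatched_control,
    max_distance = if (nrow(x$pairs)) max(x$pairs$distance) else NA_real_
  )
}

matched_ids <- function(matched) {
  c(matched$pairs$treated_id, matched$pairs$control_id)
}

#' Treatment effect in the matched cohort
#'
#' Effect of admission on the outcome restricted to matched patients. On the
#' odds-ratio scale this is a logistic regression of outcome on treatment
#' over the matched set (exponentiated slope, Wald interval); on the
#' risk-difference scale it is the difference in matched arm proportions
#' with a normal-approximation interval.
#'
#' @param cohort Cohort tibble.
#' @param matched A [match_without_replacement()] result.
#' @param scale `"OR"` or `"RD"`.
#' @param level Confidence level.
#' @return A one-row effect tibble (see [effect_estimate()]).
#' @export
matched_effect <- function(cohort, matched, scale = c("OR", "RD"), level = 0.95) {
  scale <- match.arg(scale)
  stopifnot(inherits(matched, "matched_cohort"))
  if (nrow(matched$pairs) < 2) {
    stop("need at least 2 matched pairs to estimate an effect", call. = FALSE)
  }
  sub <- dplyr::filter(cohort, .data$patient_id %in% matched_ids(matched))
  if (length(unique(sub$outcome)) < 2) {
    stop("matched-set outcome is degenerate (single value)", call. = FALSE)
  }
  if (scale == "OR") {
    fit <- fit_logistic(matrix(sub$treatment, ncol = 1,
                               dimnames = list(NULL, "treatment")),
                        as.numeric(sub$outcome))
    b <- fit$coefficients["treatment"]
    se <- sqrt(fit$covariance["treatment", "treatment"])
    zq <- qnorm(1 - (1 - level) / 2)
    effect_estimate("ps_matched", "OR", exp(b),
                    ci_low = exp(b - zq * se), ci_high = exp(b + zq * se),
                    level = level, p_value = 2 * pnorm(-abs(b / se)),
                    n_used = nrow(sub), ci_method = "wald_analytic")
  } else {
    prop_diff_estimate(sub, "ps_matched", level = level)
  }
}

# difference of outcome proportions, admitted minus refused, normal CI
prop_diff_estimate <- function(cohort, estimator, level = 0.95) {
  y1 <- cohort$outcome[cohort$treatment == 1]
  y0 <- cohort$outcome[cohort$treatment == 0]
  p1 <- mean(y1); p0 <- mean(y0)
  se <- sqrt(p1 * (1 - p1) / length(y1) + p0 * (1 - p0) / length(y0))
  zq <- qnorm(1 - (1 - level) / 2)
  rd <- p1 - p0
  p_value <- if (se > 0) 2 * pnorm(-abs(rd / se)) else as.numeric(rd == 0)
  effect_estimate(estimator, "RD", rd,
                  ci_low = rd - zq * se, ci_high = rd + zq * se,
                  level = level, p_value = p_value,
                  n_used = nrow(cohort), ci_method = "wald_analytic")
}

#' @export
#' @method autoplot iv_balance
autoplot.iv_balance <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$d))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$covariate)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-0.1, 0.1), linetype = 3,
                        colour = "grey70") +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::labs(
      x = "Standardized difference",
      y = NULL,
      title = paste0("Covariate balance (stratified by ", attr(object, "by"), ")")
    ) +
    ggplot2::theme_minimal()
}
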