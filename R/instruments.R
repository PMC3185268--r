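#' Standardized difference between two groups
#'
#' Covariate-balance diagnostic: the between-group difference in means (or
#' proportions) scaled by the pooled spread,
#' \deqn{d = (\bar w_1 - \bar w_0) / \sqrt{(s_1^2 + s_0^2)/2}}
#' for a continuous covariate and
#' \deqn{d = (p_1 - p_0) / \sqrt{(p_1(1-p_1) + p_0(1-p_0))/2}}
#' for a binary one. When both groups have zero variance the difference is
#' undefined and `NA` is returned (balance tables exclude such covariates
#' from their mean absolute d).
#'
#' @param group1,group0 Numeric vectors of covariate values in each group
#'   (group 1 conventionally the admitted arm, so the sign is
#'   admitted-minus-refused).
#' @param kind `"continuous"` or `"binary"`; `"auto"` treats a 0/1-valued
#'   covariate as binary.
#' @return A single standardized difference, possibly `NA`.
#' @examples
#' standardized_difference(rnorm(50, 1), rnorm(50, 0))
#' standardized_difference(c(1, 1, 0, 1), c(0, 1, 0, 0), kind = "binary")
#' @export
standardized_difference <- function(group1, group0,
                                    kind = c("auto", "continuous", "binary")) {
  kind <- match.arg(kind)
  group1 <- as.numeric(group1); group0 <- as.numeric(group0)
  if (length(group1) < 2 || length(group0) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (kind == "auto") {
    kind <- if (all(c(group1, group0) %in% c(0, 1))) "binary" else "continuous"
  }
  if (kind == "binary") {
    p1 <- mean(group1); p0 <- mean(group0)
    denom2 <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
    num <- p1 - p0
  } else {
    denom2 <- (stats::var(group1) + stats::var(group0)) / 2
    num <- mean(group1) - mean(group0)
  }
  if (denom2 <= 0) {
    if (num == 0) return(0) # equal constants: balanced by definition
    return(NA_real_)
  }
  num / sqrt(denom2)
}

#' Covariate balance table
#'
#' Standardized differences for a set of covariates, stratified by any
#' binary column — the actual treatment (the usual Table-1 diagnostic), a
#' candidate instrument (the instrument-validity diagnostic), or treatment
#' within a matched subset. The mean absolute standardized difference is
#' attached as attribute `"mean_abs_d"` and reported by [glance()].
#'
#' @param cohort Cohort tibble.
#' @param covariate_names Character vector of covariate columns.
#' @param by Name of the binary stratifying column (default `"treatment"`).
#' @param ids Optional vector of `patient_id`s restricting the table to a
#'   subset (e.g. a matched cohort).
#' @return A tibble of class `"iv_balance"` with columns `covariate`,
#'   `kind`, `mean_1`, `mean_0`, `d`.
#' @examples
#' cfg <- eldicus_sim_config(n_patients = 1500)
#' co <- simulate_cohort(cfg)
#' balance_table(co, c("age", "sofa", "gcs"))
#' @export
balance_table <- function(cohort, covariate_names, by = "treatment", ids = NULL) {
  check_columns(cohort, c(covariate_names, by, if (!is.null(ids)) "patient_id"))
  if (!is.null(ids)) cohort <- dplyr::filter(cohort, .data$patient_id %in% ids)
  g <- cohort[[by]]
  if (!all(g %in% c(0, 1)) || length(unique(g)) < 2) {
    stop("`by` column '", by, "' must be binary 0/1 with both groups present",
         call. = FALSE)
  }
  rows <- purrr::map(covariate_names, function(nm) {
    w <- cohort[[nm]]
    kind <- if (all(w %in% c(0, 1))) "binary" else "continuous"
    tibble::tibble(
      covariate = nm,
      kind = kind,
      mean_1 = mean(w[g == 1]),
      mean_0 = mean(w[g == 0]),
      d = standardized_difference(w[g == 1], w[g == 0], kind)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- structure(out, class = c("iv_balance", class(out)))
  attr(out, "mean_abs_d") <- mean(abs(out$d), na.rm = TRUE)
  attr(out, "by") <- by
  out
}

#' @export
#' @method glance iv_balance
glance.iv_balance <- function(x, ...) {
  tibble::tibble(
    by = attr(x, "by"),
    n_covariates = nrow(x),
    n_undefined = sum(is.na(x$d)),
    mean_abs_d = attr(x, "mean_abs_d")
  )
}

#' First-stage strength of a candidate instrument
#'
#' Linear first-stage regression of the (0/1-coded) treatment on the
#' instrument and covariates. Reports the partial F-statistic of the
#' instrument (the squared t-statistic, in this single-instrument case), its
#' p-value, the squared partial correlation between instrument and treatment
#' given the covariates, and the first-stage coefficient with its standard
#' error. A partial F below 10 is the conventional weak-instrument flag.
#'
#' @param cohort Cohort tibble with a 0/1 `treatment` column.
#' @param z_name Instrument column name.
#' @param covariate_names Covariates to condition on (may be empty).
#' @return A one-row tibble: `instrument`, `first_stage_coef`, `first_stage_se`,
#'   `partial_f`, `partial_f_p`, `partial_r2`, `weak`.
#' @export
first_stage_strength <- function(cohort, z_name, covariate_names = character()) {
  check_columns(cohort, c("treatment", z_name, covariate_names))
  X <- as.matrix(cohort[, c(z_name, covariate_names), drop = FALSE])
  fit <- tryCatch(
    fit_linear(X, as.numeric(cohort$treatment)),
    error = function(e) {
      stop("first-stage regression failed (instrument collinear with covariates?): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  b <- fit$coefficients[z_name]
  se <- sqrt(fit$covariance[z_name, z_name])
  t_stat <- b / se
  df <- fit$n_obs - length(fit$coefficients)
  partial_f <- unname(t_stat^2)
  tibble::tibble(
    instrument = z_name,
    first_stage_coef = unname(b),
    first_stage_se = unname(se),
    partial_f = partial_f,
    partial_f_p = stats::pf(partial_f, 1, df, lower.tail = FALSE),
    partial_r2 = partial_f / (partial_f + df),
    weak = partial_f < 10
  )
}

#' Instrument-on-treatment odds ratio
#'
#' Univariate logistic regression of treatment on a binary instrument; the
#' exponentiated slope with its Wald 95% interval, the odds-ratio analogue
#' of first-stage strength for a naturally binary treatment.
#'
#' @inheritParams first_stage_strength
#' @param level Confidence level.
#' @return One-row tibble: `instrument`, `or`, `ci_low`, `ci_high`.
#' @export
instrument_treatment_or <- function(cohort, z_name, level = 0.95) {
  check_columns(cohort, c("treatment", z_name))
  z <- cohort[[z_name]]
  if (!all(z %in% c(0, 1)) || length(unique(z)) < 2) {
    stop("instrument '", z_name, "' must be binary with both strata non-empty",
         call. = FALSE)
  }
  fit <- fit_logistic(matrix(z, ncol = 1, dimnames = list(NULL, z_name)),
                      as.numeric(cohort$treatment))
  b <- fit$coefficients[z_name]
  se <- sqrt(fit$covariance[z_name, z_name])
  zq <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    instrument = z_name,
    or = unname(exp(b)),
    ci_low = unname(exp(b - zq * se)),
    ci_high = unname(exp(b + zq * se))
  )
}

#' Dichotomize a grouping column by its admission rate
#'
#' Builds a candidate instrument from a categorical column (e.g. country of
#' enrolment): each group's admission rate is computed and groups at or
#' above the threshold are coded 1 ("high admission rate"), the rest 0. The
#' default threshold of 0.85 follows the convention of splitting a triage
#' cohort into two roughly equal halves; [balanced_rate_threshold()] scans
#' the observed group rates for the cut that makes the split most even.
#'
#' @param cohort Cohort tibble.
#' @param group_column Name of the categorical column.
#' @param threshold Admission-rate cut point.
#' @param new_name Name of the new binary column (default
#'   `<group_column>_high_rate`).
#' @return The cohort with the new 0/1 column appended.
#' @export
dichotomize_by_group_rate <- function(cohort, group_column, threshold = 0.85,
                                      new_name = NULL) {
  check_columns(cohort, c("treatment", group_column))
  new_name <- new_name %||% paste0(group_column, "_high_rate")
  rates <- group_admission_rates(cohort, group_column)
  if (nrow(rates) < 2) {
    warning("'", group_column, "' has a single level; candidate instrument is degenerate")
  }
  high <- rates$group[rates$rate >= threshold]
  out <- dplyr::mutate(cohort,
                       !!new_name := as.integer(.data[[group_column]] %in% high))
  if (length(unique(out[[new_name]])) < 2) {
    warning("dichotomized candidate '", new_name,
            "' is constant at threshold ", threshold, "; flagged degenerate")
  }
  out
}

group_admission_rates <- function(cohort, group_column) {
  cohort |>
    dplyr::group_by(group = .data[[group_column]]) |>
    dplyr::summarise(rate = mean(.data$treatment), n = dplyr::n(),
                     .groups = "drop")
}

#' @rdname dichotomize_by_group_rate
#' @return `balanced_rate_threshold()`: the admission-rate threshold (one of
#'   the observed group rates) that divides the cohort into two groups of the
#'   most nearly equal size.
#' @export
balanced_rate_threshold <- function(cohort, group_column) {
  rates <- group_admission_rates(cohort, group_column)
  n_total <- nrow(cohort)
  cuts <- sort(unique(rates$rate))
  imbalance <- purrr::map_dbl(cuts, function(cut) {
    n_high <- sum(rates$n[rates$rate >= cut])
    abs(n_high - (n_total - n_high))
  })
  cuts[which.min(imbalance)]
}

#' Evaluate and rank candidate instruments
#'
#' One diagnostic report per candidate: the univariate instrument-on-treatment
#' odds ratio, the first-stage coefficient, partial F and partial r-squared,
#' and covariate balance stratified by the instrument versus by the actual
#' treatment. Candidates are ranked lexicographically: non-weak instruments
#' (partial F >= 10) first, then smaller mean absolute standardized
#' difference across instrument strata (less residual confounding of the
#' instrument), then larger partial F.
#'
#' @param cohort Cohort tibble.
#' @param candidate_names Character vector of binary candidate columns.
#' @param covariate_names Covariates used both in the first stage and in the
#'   balance assessment.
#' @return A tibble of class `"instrument_report"`, one row per candidate in
#'   rank order, with list-columns `balance_by_iv` and `balance_by_treatment`
#'   holding the full per-covariate tables.
#' @examples
#' co <- simulate_cohort(eldicus_sim_config(n_patients = 2000))
#' evaluate_instruments(co, "physician_specialty", c("age", "sofa"))
#' @export
evaluate_instruments <- function(cohort, candidate_names, covariate_names) {
  stopifnot(length(candidate_names) >= 1)
  rows <- purrr::map(candidate_names, function(znm) {
    strength <- first_stage_strength(cohort, znm, covariate_names)
    or <- instrument_treatment_or(cohort, znm)
    b_iv <- balance_table(cohort, covariate_names, by = znm)
    b_tx <- balance_table(cohort, covariate_names, by = "treatment")
    dplyr::bind_cols(
      strength,
      dplyr::select(or, -"instrument"),
      tibble::tibble(
        mean_abs_d_by_iv = attr(b_iv, "mean_abs_d"),
        mean_abs_d_by_treatment = attr(b_tx, "mean_abs_d"),
        balance_by_iv = list(b_iv),
        balance_by_treatment = list(b_tx)
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$weak, out$mean_abs_d_by_iv, -out$partial_f), ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("instrument_report", class(out)))
}

#' @export
#' @method autoplot instrument_report
autoplot.instrument_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "instrument", "partial_f",
                  "mean_abs_d_by_iv", "mean_abs_d_by_treatment"),
    -"instrument", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$instrument, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Candidate-instrument diagnostics") +
    ggplot2::theme_minimal()
}

check_columns <- function(cohort, cols) {
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(cohort)
}
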