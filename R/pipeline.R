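#' Crude and covariate-adjusted effect of admission
#'
#' The standard regression arm of the analysis. On the odds-ratio scale:
#' logistic regression of outcome on treatment, without and with baseline
#' covariates (exponentiated treatment slope, Wald interval). On the
#' risk-difference scale: the crude estimate is the difference in arm
#' proportions (admitted minus refused) with a normal-approximation
#' interval; the adjusted estimate is the treatment coefficient from a
#' linear probability model of outcome on treatment and covariates.
#'
#' @param cohort Cohort tibble.
#' @param covariate_names Adjustment covariates.
#' @param scale `"OR"` or `"RD"`.
#' @param level Confidence level.
#' @return A two-row effect tibble (`crude`, `adjusted`).
#' @examples
#' co <- simulate_cohort(eldicus_sim_config(n_patients = 2000))
#' crude_and_adjusted(co, c("age", "sofa", "saps", "gcs", "karnofsky"), "OR")
#' @export
crude_and_adjusted <- function(cohort, covariate_names,
                               scale = c("OR", "RD"), level = 0.95) {
  scale <- match.arg(scale)
  xy <- cohort_xy(cohort)
  check_columns(cohort, covariate_names)
  for (arm in c(0, 1)) {
    if (length(unique(xy$y[xy$x == arm])) < 2) {
      stop("degenerate outcome in the ", c("refused", "admitted")[arm + 1],
           " arm", call. = FALSE)
    }
  }
  W <- design_of(cohort, covariate_names)
  zq <- qnorm(1 - (1 - level) / 2)
  slope_estimate <- function(fit, estimator, transform) {
    b <- fit$coefficients["treatment"]
    se <- sqrt(fit$covariance["treatment", "treatment"])
    effect_estimate(estimator, scale, transform(b),
                    ci_low = transform(b - zq * se),
                    ci_high = transform(b + zq * se),
                    level = level, p_value = 2 * pnorm(-abs(b / se)),
                    n_used = nrow(cohort), ci_method = "wald_analytic")
  }
  x_col <- matrix(xy$x, ncol = 1, dimnames = list(NULL, "treatment"))
  if (scale == "OR") {
    crude <- slope_estimate(fit_logistic(x_col, xy$y), "crude", exp)
    adjusted <- slope_estimate(fit_logistic(cbind(x_col, W), xy$y), "adjusted", exp)
  } else {
    crude <- prop_diff_estimate(cohort, "crude", level = level)
    adjusted <- slope_estimate(fit_linear(cbind(x_col, W), xy$y), "adjusted",
                               identity)
  }
  dplyr::bind_rows(crude, adjusted)
}

#' Percentile-bootstrap inference for an estimator
#'
#' Re-runs an estimator on resampled cohorts and attaches a percentile
#' confidence interval and a two-sided bootstrap p-value to its full-data
#' point estimate. Resampling is of patients with replacement, or of whole
#' clusters when a cluster column is named (every row of each sampled
#' cluster enters the replicate, clusters drawn with replacement). The
#' p-value is the percentile-crossing construction with a +1 continuity
#' correction: `2 * min((#reps <= null) + 1, (#reps >= null) + 1) / (B_ok + 1)`,
#' where the null is 0 on the risk-difference scale and 1 on the odds-ratio
#' scale. Replicates where the estimator fails (for example a zero Wald
#' denominator in a resample) are dropped and counted; inference is refused
#' when more than 20% of replicates fail.
#'
#' @param cohort Cohort tibble.
#' @param estimator_fn Function taking a cohort tibble and returning a
#'   one-row effect tibble, e.g. `\(d) wald_estimator(d, "z")`.
#' @param B Bootstrap iterations (the reference analysis uses 1,000).
#' @param cluster_name Optional cluster column for cluster resampling.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return The estimator's one-row effect tibble with percentile `ci_low`,
#'   `ci_high`, bootstrap `p_value`, `ci_method = "bootstrap_percentile"`,
#'   and attributes `n_failed` and `replicates`.
#' @examples
#' co <- simulate_cohort(eldicus_sim_config(n_patients = 1500))
#' bootstrap_ci(co, \(d) wald_estimator(d, "physician_specialty"), B = 50)
#' @export
bootstrap_ci <- function(cohort, estimator_fn, B = 1000, cluster_name = NULL,
                         seed = 1L, level = 0.95) {
  stopifnot(B >= 1)
  base <- estimator_fn(cohort)
  stopifnot(inherits(base, "effect_estimate"), nrow(base) == 1)
  if (!is.null(cluster_name)) {
    check_columns(cohort, cluster_name)
    cl <- cohort[[cluster_name]]
    cl_rows <- split(seq_len(nrow(cohort)), cl)
  }
  reps <- withr::with_seed(as.integer(seed), {
    purrr::map_dbl(seq_len(B), function(b) {
      idx <- if (is.null(cluster_name)) {
        sample.int(nrow(cohort), replace = TRUE)
      } else {
        picked <- sample(length(cl_rows), replace = TRUE)
        unlist(cl_rows[picked], use.names = FALSE)
      }
      tryCatch(
        suppressWarnings(estimator_fn(cohort[idx, , drop = FALSE])$point),
        error = function(e) NA_real_
      )
    })
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.2 * B) {
    stop("bootstrap inference refused: ", n_failed, " of ", B,
         " replicates failed (> 20%)", call. = FALSE)
  }
  ok <- reps[!is.na(reps)]
  alpha <- 1 - level
  ci <- unname(quantile(ok, c(alpha / 2, 1 - alpha / 2), type = 7))
  null_value <- if (base$scale == "RD") 0 else 1
  n_le <- sum(ok <= null_value)
  n_ge <- sum(ok >= null_value)
  p <- min(1, 2 * min(n_le + 1, n_ge + 1) / (length(ok) + 1))
  out <- base
  out$ci_low <- ci[1]
  out$ci_high <- ci[2]
  out$level <- level
  out$p_value <- p
  out$ci_method <- "bootstrap_percentile"
  attr(out, "n_failed") <- n_failed
  attr(out, "replicates") <- ok
  out
}

#' Describe a full triage analysis
#'
#' Bundles everything [run_full_analysis()] needs: the cohort source (a CSV
#' path or a [sim_config()]), column roles, the adjustment covariates,
#' candidate instruments, estimators, and bootstrap settings.
#'
#' @param cohort_path Path to a cohort CSV (exclusive with `sim_config`).
#' @param sim_config A [sim_config()] to simulate the cohort from.
#' @param treatment,outcome,patient_id Column names for the core roles.
#' @param covariates Adjustment/propensity covariate names.
#' @param instruments Candidate instrument column names (>= 1).
#' @param estimators IV estimators to run, a subset of
#'   `c("wald", "2sls", "2lr", "probit2", "3ls")`.
#' @param cluster Optional cluster column for the bootstrap.
#' @param bootstrap_iterations Bootstrap replicates per IV estimator
#'   (reference value 1,000).
#' @param bootstrap_seed Seed for all bootstrap resampling.
#' @param match_seed Seed for the matching order.
#' @param level Confidence level.
#' @param binary_map Optional named character vector mapping string levels
#'   to 0/1 for treatment/outcome columns read from CSV, e.g.
#'   `c(yes = "1", no = "0")`.
#' @return An `"analysis_config"` list.
#' @export
analysis_config <- function(cohort_path = NULL, sim_config = NULL,
                            treatment = "treatment", outcome = "outcome",
                            patient_id = "patient_id",
                            covariates = character(),
                            instruments,
                            estimators = c("wald", "2sls", "2lr", "probit2", "3ls"),
                            cluster = NULL,
                            bootstrap_iterations = 1000,
                            bootstrap_seed = 20110921,
                            match_seed = 1L,
                            level = 0.95,
                            binary_map = NULL) {
  if (is.null(cohort_path) == is.null(sim_config)) {
    stop("give exactly one of `cohort_path` or `sim_config`", call. = FALSE)
  }
  estimators <- match.arg(estimators,
                          c("wald", "2sls", "2lr", "probit2", "3ls"),
                          several.ok = TRUE)
  stopifnot(bootstrap_iterations >= 1, length(instruments) >= 1)
  structure(
    list(cohort_path = cohort_path, sim_config = sim_config,
         treatment = treatment, outcome = outcome, patient_id = patient_id,
         covariates = covariates, instruments = instruments,
         estimators = estimators, cluster = cluster,
         bootstrap_iterations = as.integer(bootstrap_iterations),
         bootstrap_seed = as.integer(bootstrap_seed),
         match_seed = as.integer(match_seed),
         level = level, binary_map = binary_map),
    class = "analysis_config"
  )
}

#' Read a cohort CSV
#'
#' Reads a patient-level cohort table and validates it against an
#' [analysis_config()]: configured columns must exist, treatment and outcome
#' must be strictly 0/1 (after the optional `binary_map` recoding), and the
#' file must be non-empty. Columns are renamed to the package's canonical
#' roles (`patient_id`, `treatment`, `outcome`, `cluster_id`).
#'
#' @param path CSV path (with header).
#' @param config An `"analysis_config"`.
#' @return A cohort tibble.
#' @export
read_cohort_csv <- function(path, config) {
  stopifnot(inherits(config, "analysis_config"))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(raw)) stop("empty cohort file: ", path, call. = FALSE)
  needed <- c(config$patient_id, config$treatment, config$outcome,
              config$covariates, config$instruments, config$cluster)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("cohort file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  decode_binary <- function(v, what) {
    if (!is.null(config$binary_map) && is.character(v)) {
      v <- unname(config$binary_map[v])
    }
    v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) | !v %in% c(0, 1))
    if (length(bad)) {
      stop("column '", what, "' is not binary 0/1 at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    as.integer(v)
  }
  out <- raw
  names(out)[names(out) == config$patient_id] <- "patient_id"
  trt <- decode_binary(raw[[config$treatment]], config$treatment)
  oc <- decode_binary(raw[[config$outcome]], config$outcome)
  if (config$treatment != "treatment") out[[config$treatment]] <- NULL
  if (config$outcome != "outcome") out[[config$outcome]] <- NULL
  out$treatment <- trt
  out$outcome <- oc
  if (!is.null(config$cluster) && config$cluster != "cluster_id") {
    names(out)[names(out) == config$cluster] <- "cluster_id"
  }
  if (anyDuplicated(out$patient_id)) {
    stop("duplicated patient_id values in ", path, call. = FALSE)
  }
  tibble::as_tibble(out)
}

iv_estimator_fn <- function(name, z_name, covariate_names) {
  switch(
    name,
    wald = function(d) wald_estimator(d, z_name),
    `2sls` = function(d) two_stage_least_squares(d, z_name, covariate_names),
    `2lr` = function(d) two_stage_logistic(d, z_name, covariate_names),
    probit2 = function(d) two_stage_probit(d, z_name, covariate_names),
    `3ls` = function(d) three_stage_ls(d, z_name, covariate_names),
    stop("unknown estimator: ", name, call. = FALSE)
  )
}

#' Run the full comparative analysis
#'
#' Executes the whole pipeline on a loaded or simulated cohort: pre-match
#' covariate balance, the propensity arm (model, caliper matching, matched
#' balance and matched effects), candidate-instrument evaluation and
#' selection, crude and adjusted estimates, and the requested IV estimators
#' with percentile-bootstrap confidence intervals using the selected (top
#' ranked) instrument. Results are assembled into an odds-ratio table
#' (crude, adjusted, PS-matched, two-stage logistic, two-stage probit) and a
#' risk-difference table (crude, adjusted, PS-matched, Wald, 2SLS, 3LS).
#' A stage that fails is recorded under `$errors` with its name and the
#' report of the completed stages is still returned.
#'
#' @param config An [analysis_config()].
#' @return An `"analysis_report"` list: `cohort_summary`, `balance_pre`,
#'   `propensity` (glance), `matched` (glance), `balance_matched`,
#'   `instruments`, `chosen_instrument`, `or_table`, `rd_table`, `errors`.
#' @examples
#' cfg <- analysis_config(
#'   sim_config = eldicus_sim_config(n_patients = 1200),
#'   covariates = c("age", "sofa", "gcs"),
#'   instruments = "physician_specialty",
#'   bootstrap_iterations = 50
#' )
#' rep <- run_full_analysis(cfg)
#' rep$rd_table
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  report <- structure(list(errors = character()), class = "analysis_report")
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  cohort <- run_stage("load_cohort", {
    if (!is.null(config$sim_config)) simulate_cohort(config$sim_config)
    else read_cohort_csv(config$cohort_path, config)
  })
  if (is.null(cohort)) return(report)
  covs <- config$covariates

  report$cohort_summary <- tibble::tibble(
    n_patients = nrow(cohort),
    n_admitted = sum(cohort$treatment),
    admission_rate = mean(cohort$treatment),
    mortality_rate = mean(cohort$outcome)
  )
  report$balance_pre <- run_stage("balance_pre",
                                  balance_table(cohort, covs, by = "treatment"))

  ps <- run_stage("propensity", fit_propensity(cohort, covs))
  matched <- NULL
  if (!is.null(ps)) {
    report$propensity <- glance(ps)
    matched <- run_stage("matching",
                         match_without_replacement(ps, cohort,
                                                   seed = config$match_seed))
  }
  ps_or <- ps_rd <- NULL
  if (!is.null(matched)) {
    report$matched <- glance(matched)
    report$balance_matched <- run_stage(
      "balance_matched",
      balance_table(cohort, covs, by = "treatment", ids = matched_ids(matched))
    )
    ps_or <- run_stage("matched_effect_or",
                       matched_effect(cohort, matched, "OR", config$level))
    ps_rd <- run_stage("matched_effect_rd",
                       matched_effect(cohort, matched, "RD", config$level))
  }

  report$instruments <- run_stage(
    "instrument_evaluation",
    evaluate_instruments(cohort, config$instruments, covs)
  )
  z_name <- if (!is.null(report$instruments)) {
    report$instruments$instrument[1]
  } else {
    config$instruments[1]
  }
  report$chosen_instrument <- z_name

  crude_adj_or <- run_stage("crude_adjusted_or",
                            crude_and_adjusted(cohort, covs, "OR", config$level))
  crude_adj_rd <- run_stage("crude_adjusted_rd",
                            crude_and_adjusted(cohort, covs, "RD", config$level))

  iv_rows <- purrr::map(config$estimators, function(est) {
    run_stage(paste0("iv_", est), {
      fn <- iv_estimator_fn(est, z_name, covs)
      suppressWarnings(
        bootstrap_ci(cohort, fn, B = config$bootstrap_iterations,
                     cluster_name = config$cluster,
                     seed = config$bootstrap_seed, level = config$level)
      )
    })
  })
  iv_tbl <- dplyr::bind_rows(purrr::compact(iv_rows))

  all_rows <- dplyr::bind_rows(crude_adj_or, ps_or, crude_adj_rd, ps_rd, iv_tbl)
  report$or_table <- dplyr::filter(all_rows, .data$scale == "OR")
  report$rd_table <- dplyr::filter(all_rows, .data$scale == "RD")
  report
}

#' @export
#' @method print analysis_report
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  if (!is.null(x$cohort_summary)) {
    with(x$cohort_summary,
         cat(sprintf("  cohort: %d patients, %.1f%% admitted, %.1f%% died\n",
                     n_patients, 100 * admission_rate, 100 * mortality_rate)))
  }
  if (!is.null(x$chosen_instrument)) {
    cat("  chosen instrument:", x$chosen_instrument, "\n")
  }
  if (!is.null(x$or_table)) {
    cat("  odds-ratio estimates:\n")
    print(as.data.frame(x$or_table[, c("estimator", "point", "ci_low",
                                       "ci_high", "p_value")]), digits = 3)
  }
  if (!is.null(x$rd_table)) {
    cat("  risk-difference estimates:\n")
    print(as.data.frame(x$rd_table[, c("estimator", "point", "ci_low",
                                       "ci_high", "p_value")]), digits = 3)
  }
  if (length(x$errors)) {
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an analysis report to TSV files
#'
#' Writes `estimates.tsv` (one row per estimator and scale with the columns
#' `estimator, scale, point, ci_low, ci_high, p_value, n, ci_method`),
#' `balance.tsv` (pre-match and, when available, matched standardized
#' differences) and `instruments.tsv` (the candidate diagnostics) into a
#' directory.
#'
#' @param report An `"analysis_report"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  est <- dplyr::bind_rows(report$or_table, report$rd_table)
  if (!is.null(est) && nrow(est)) {
    est_out <- dplyr::select(est, "estimator", "scale", "point", "ci_low",
                             "ci_high", "p_value", n = "n_used", "ci_method")
    p <- file.path(dir, "estimates.tsv")
    readr::write_tsv(est_out, p)
    paths <- c(paths, p)
  }
  bal <- dplyr::bind_rows(
    if (!is.null(report$balance_pre)) {
      dplyr::mutate(tibble::as_tibble(report$balance_pre), set = "pre_match")
    },
    if (!is.null(report$balance_matched)) {
      dplyr::mutate(tibble::as_tibble(report$balance_matched), set = "matched")
    }
  )
  if (!is.null(bal) && nrow(bal)) {
    p <- file.path(dir, "balance.tsv")
    readr::write_tsv(bal, p)
    paths <- c(paths, p)
  }
  if (!is.null(report$instruments)) {
    ins <- dplyr::select(tibble::as_tibble(report$instruments),
                         -"balance_by_iv", -"balance_by_treatment")
    p <- file.path(dir, "instruments.tsv")
    readr::write_tsv(ins, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Forest plot of an analysis report
#'
#' One panel per effect scale, estimators on the vertical axis, point
#' estimates with their confidence intervals; the null (OR 1, RD 0) is the
#' dashed reference line.
#'
#' @param object An `"analysis_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot analysis_report
autoplot.analysis_report <- function(object, ...) {
  df <- dplyr::bind_rows(object$or_table, object$rd_table)
  df$null <- ifelse(df$scale == "OR", 1, 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$point, y = .data$estimator)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$null),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~scale, scales = "free_x") +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL,
                  title = "Effect of ICU admission on hospital mortality") +
    ggplot2::theme_minimal()
}
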