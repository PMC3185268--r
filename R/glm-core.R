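#' Minimal regression engine
#'
#' `fit_linear()`, `fit_logistic()` and `fit_probit()` are thin, strictly
#' contracted fits on which every estimator stage of the package is built.
#' All three take a numeric covariate matrix *without* an intercept column
#' (one is always prepended) and return a `"reg_fit"` object carrying the
#' coefficients, their covariance, response-scale fitted values and a
#' convergence flag. Non-convergence — including quasi-complete separation of
#' a binary response — is an error, never a silently returned fit.
#'
#' For the linear fit the coefficient covariance is the classical
#' \eqn{\hat\sigma^2 (D^\top D)^{-1}} with the residual variance on
#' \eqn{n - p} degrees of freedom. For the binomial fits it is the inverse
#' observed information at the maximum-likelihood solution.
#'
#' @param design Numeric matrix (or data frame coercible to one) of
#'   covariates, one row per observation. May have zero columns for an
#'   intercept-only fit. Column names are kept; unnamed columns are named
#'   `x1, x2, ...`.
#' @param response Numeric response vector. For `fit_logistic()` and
#'   `fit_probit()` it must be coded 0/1 with both values present.
#' @return A `"reg_fit"` object: a list with elements `family` (`"linear"`,
#'   `"logistic"` or `"probit"`), `coefficient_names`, `coefficients`,
#'   `covariance`, `fitted_values` (response scale), `n_obs`, `converged`.
#' @examples
#' f <- fit_linear(matrix(0:2, ncol = 1), c(0, 1, 3))
#' coef(f)
#' tidy(f)
#' @name glm_core
NULL

MAX_STD_COEF <- 15 # |coef| on sd-standardised inputs beyond this => separation

as_design <- function(design, n_required = NULL) {
  if (is.data.frame(design)) design <- as.matrix(design)
  if (is.null(design)) design <- matrix(numeric(0), nrow = n_required %||% 0, ncol = 0)
  if (is.vector(design)) design <- matrix(design, ncol = 1)
  if (!is.matrix(design) || !is.numeric(design)) {
    stop("`design` must be a numeric matrix of covariates", call. = FALSE)
  }
  cn <- colnames(design)
  if (is.null(cn)) cn <- if (ncol(design)) paste0("x", seq_len(ncol(design))) else character(0)
  cn[!nzchar(cn)] <- paste0("x", which(!nzchar(cn)))
  colnames(design) <- cn
  design
}

# prepend intercept, check dimensions and rank; returns the full design
full_design <- function(design, response) {
  n <- length(response)
  if (nrow(design) != n) {
    stop("design has ", nrow(design), " rows but response has length ", n, call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, design)
  p <- ncol(X)
  if (n < p) {
    stop("more coefficients (", p, ") than observations (", n, ")", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  X
}

new_reg_fit <- function(family, X, coefficients, covariance, fitted_values, converged) {
  structure(
    list(
      family = family,
      coefficient_names = colnames(X),
      coefficients = stats::setNames(as.numeric(coefficients), colnames(X)),
      covariance = covariance,
      fitted_values = as.numeric(fitted_values),
      n_obs = nrow(X),
      converged = converged
    ),
    class = "reg_fit"
  )
}

#' @rdname glm_core
#' @export
fit_linear <- function(design, response) {
  response <- as.numeric(response)
  X <- full_design(as_design(design, length(response)), response)
  fit <- stats::lm.fit(X, response)
  p <- ncol(X)
  rss <- sum(fit$residuals^2)
  df <- length(response) - p
  sigma2 <- if (df > 0) rss / df else 0
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  new_reg_fit("linear", X, fit$coefficients, sigma2 * XtX_inv,
              fit$fitted.values, converged = TRUE)
}

check_binary_response <- function(response) {
  response <- as.numeric(response)
  if (anyNA(response) || !all(response %in% c(0, 1))) {
    stop("response must be coded 0/1 with no missing values", call. = FALSE)
  }
  if (length(unique(response)) < 2) {
    stop("response is single-valued; both outcome classes are required", call. = FALSE)
  }
  response
}

fit_binomial <- function(design, response, link, check_separation = TRUE) {
  response <- check_binary_response(response)
  X <- full_design(as_design(design, length(response)), response)
  fam <- stats::binomial(link = link)
  fit <- stats::glm.fit(X, response, family = fam,
                        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  family_label <- if (link == "logit") "logistic" else "probit"
  if (!fit$converged || any(!is.finite(fit$coefficients))) {
    stop(family_label, " fit did not converge", call. = FALSE)
  }
  # separation check on the standardised scale: coef * sd(column)
  if (check_separation && ncol(X) > 1) {
    sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    std_coef <- fit$coefficients[-1] * ifelse(sds > 0, sds, 1)
    if (any(abs(std_coef) > MAX_STD_COEF)) {
      bad <- colnames(X)[-1][abs(std_coef) > MAX_STD_COEF]
      stop(family_label, " fit shows (quasi-)complete separation in: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  p <- ncol(X)
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  cov <- chol2inv(R) # inverse of X' W X from the final IWLS step
  dimnames(cov) <- list(colnames(X), colnames(X))
  new_reg_fit(family_label, X, fit$coefficients, cov, fit$fitted.values,
              converged = TRUE)
}

#' @rdname glm_core
#' @export
fit_logistic <- function(design, response) fit_binomial(design, response, "logit")

#' @rdname glm_core
#' @export
fit_probit <- function(design, response) fit_binomial(design, response, "probit")

# prediction-only first-stage fits: a separated first stage still yields
# usable fitted probabilities (its predictions degenerate towards 0/1
# monotonically), so the separation guard is applied only to fits whose
# coefficients are reported
predict_logistic <- function(design, response) {
  suppressWarnings(fit_binomial(design, response, "logit", check_separation = FALSE))
}
predict_probit <- function(design, response) {
  suppressWarnings(fit_binomial(design, response, "probit", check_separation = FALSE))
}

#' @export
#' @method coef reg_fit
coef.reg_fit <- function(object, ...) object$coefficients

#' @export
#' @method vcov reg_fit
vcov.reg_fit <- function(object, ...) object$covariance

#' @export
#' @method print reg_fit
print.reg_fit <- function(x, ...) {
  cat("<reg_fit> ", x$family, " fit, n = ", x$n_obs, "\n", sep = "")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Tidy a `reg_fit`
#'
#' Broom-style one-row-per-term summary with Wald statistics.
#'
#' @param x A `"reg_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
#' @method tidy reg_fit
tidy.reg_fit <- function(x, ...) {
  se <- sqrt(diag(x$covariance))
  z <- x$coefficients / se
  tibble::tibble(
    term = x$coefficient_names,
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' Glance at a `reg_fit`
#'
#' @param x A `"reg_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with `family`, `n_obs`, `n_terms`, `converged`.
#' @export
#' @method glance reg_fit
glance.reg_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_obs = x$n_obs,
    n_terms = length(x$coefficients),
    converged = x$converged
  )
}
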