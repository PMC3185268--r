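# Shared fixtures, all generated in code.

# A quick hand-rolled cohort with a binary instrument and dependent binary
# treatment/outcome; no package machinery involved, so it can serve as input
# to identity and oracle tests.
random_binary_cohort <- function(n, seed, gamma_z = 0.8) {
  withr::with_seed(seed, {
    z <- rbinom(n, 1, 0.5)
    x <- rbinom(n, 1, plogis(-0.2 + gamma_z * z))
    y <- rbinom(n, 1, plogis(-0.5 + 0.3 * x))
    tibble::tibble(patient_id = seq_len(n), treatment = x, outcome = y, z = z)
  })
}

# Cohort with exact stratum means: counts are chosen so the group means are
# the stated proportions exactly.
cohort_from_counts <- function(n1, y1_events, x1_treated, n0, y0_events, x0_treated) {
  mk <- function(n, events, treated, z) {
    tibble::tibble(
      treatment = rep(c(1, 0), c(treated, n - treated)),
      outcome = c(rep(c(1, 0), c(events, n - events))),
      z = z
    )
  }
  out <- dplyr::bind_rows(mk(n1, y1_events, x1_treated, 1),
                          mk(n0, y0_events, x0_treated, 0))
  out$patient_id <- seq_len(nrow(out))
  out
}

# A confounded simulation config used across propensity/balance tests:
# latent U drives both admission and death, true effect null.
confounded_config <- function(n, seed = 1L, beta_x = 0, gamma_u = 1, alpha_u = 1) {
  sim_config(
    n_patients = n, seed = seed,
    instrument_prevalence = 0.5,
    covariates = data.frame(
      name = c("sev1", "sev2"), kind = "gaussian",
      location = c(0, 0), scale = c(1, 1)
    ),
    confounder_sd = 1,
    treatment_model = list(intercept = 0.3, instrument = 0.8,
                           covariates = c(sev1 = 0.7, sev2 = -0.4),
                           confounder = gamma_u),
    outcome_kind = "logistic",
    outcome_model = list(intercept = -1, treatment = beta_x,
                         covariates = c(sev1 = 0.6, sev2 = -0.3),
                         confounder = alpha_u)
  )
}

# Linear-probability config with an exact risk-difference truth; the
# covariate w is a measured confounder, U the latent one.
lp_config <- function(n, seed = 1L, beta_x = 0, gamma_z = 0.8,
                      gamma_u = 1, alpha_u = 1, confounder_sd = 0.12) {
  sim_config(
    n_patients = n, seed = seed,
    instrument_prevalence = 0.5,
    covariates = data.frame(name = "w", kind = "gaussian",
                            location = 0, scale = 1),
    confounder_sd = confounder_sd,
    treatment_model = list(intercept = 0, instrument = gamma_z,
                           covariates = c(w = 1), confounder = gamma_u),
    outcome_kind = "linear_probability",
    outcome_model = list(intercept = 0.5, treatment = beta_x,
                         covariates = c(w = 0.1), confounder = alpha_u)
  )
}

expect_one_row_estimate <- function(est, estimator, scale) {
  expect_s3_class(est, "effect_estimate")
  expect_equal(nrow(est), 1L)
  expect_identical(est$estimator, estimator)
  expect_identical(est$scale, scale)
}
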