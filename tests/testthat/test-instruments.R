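test_that("first-stage strength matches a hand-computed bivariate regression", {
  # X = (0,0,1,1,1,1), Z = (0,0,0,1,1,1): slope 2/3, se 1/3, t = 2, F = 4
  co <- tibble::tibble(patient_id = 1:6,
                       treatment = c(0, 0, 1, 1, 1, 1),
                       outcome = c(0, 1, 0, 1, 0, 1),
                       z = c(0, 0, 0, 1, 1, 1))
  fs <- first_stage_strength(co, "z")
  expect_equal(fs$first_stage_coef, 2 / 3, tolerance = 1e-12)
  expect_equal(fs$first_stage_se, 1 / 3, tolerance = 1e-12)
  expect_equal(fs$partial_f, 4, tolerance = 1e-12)
  expect_equal(fs$partial_r2, 4 / (4 + 4), tolerance = 1e-12) # t^2/(t^2 + df)
  expect_true(fs$weak)
})

test_that("partial F equals the nested-model sum-of-squares F to 1e-8", {
  for (seed in 1:8) {
    co <- withr::with_seed(seed, tibble::tibble(
      patient_id = 1:60,
      treatment = rbinom(60, 1, 0.5),
      outcome = rbinom(60, 1, 0.5),
      z = rbinom(60, 1, 0.4),
      w1 = rnorm(60), w2 = rnorm(60)
    ))
    if (length(unique(co$treatment)) < 2) next
    fs <- first_stage_strength(co, "z", c("w1", "w2"))
    # brute-force ANOVA decomposition between nested OLS models
    full <- stats::lm(treatment ~ z + w1 + w2, data = co)
    red <- stats::lm(treatment ~ w1 + w2, data = co)
    rss1 <- sum(stats::residuals(full)^2)
    rss0 <- sum(stats::residuals(red)^2)
    f_nested <- (rss0 - rss1) / (rss1 / stats::df.residual(full))
    expect_equal(fs$partial_f, f_nested, tolerance = 1e-8)
    # partial F is the squared t-statistic of z
    t_z <- summary(full)$coefficients["z", "t value"]
    expect_equal(fs$partial_f, t_z^2, tolerance = 1e-8)
  }
})

test_that("a useless instrument has near-zero partial F and r2 at large n", {
  co <- withr::with_seed(17, tibble::tibble(
    patient_id = 1:20000,
    treatment = rbinom(20000, 1, 0.6),
    outcome = rbinom(20000, 1, 0.3),
    z = rbinom(20000, 1, 0.5)
  ))
  fs <- first_stage_strength(co, "z")
  expect_lt(fs$partial_f, 7)
  expect_lt(fs$partial_r2, 5e-4)
  expect_true(fs$weak)
})

test_that("marginal r2 is not larger than partial r2 computed on the same data", {
  # shrinking the conditioning set to empty relates partial to marginal
  # correlation; verified against a brute-force partial-correlation formula
  co <- withr::with_seed(23, {
    w <- rnorm(300)
    z <- rbinom(300, 1, plogis(0.5 * w))
    x <- rbinom(300, 1, plogis(0.4 + 0.9 * z + 0.8 * w))
    tibble::tibble(patient_id = 1:300, treatment = x,
                   outcome = rbinom(300, 1, 0.3), z = z, w = w)
  })
  r2_partial <- first_stage_strength(co, "z", "w")$partial_r2
  rz <- stats::residuals(stats::lm(z ~ w, data = co))
  rx <- stats::residuals(stats::lm(treatment ~ w, data = co))
  expect_equal(r2_partial, cor(rz, rx)^2, tolerance = 1e-6)
  r2_marginal <- first_stage_strength(co, "z")$partial_r2
  expect_equal(r2_marginal, cor(co$z, co$treatment)^2, tolerance = 1e-6)
})

test_that("instrument-on-treatment OR is the 2x2 cross-product ratio", {
  co <- cohort_from_counts(n1 = 100, y1_events = 30, x1_treated = 80,
                           n0 = 100, y0_events = 30, x0_treated = 60)
  or <- instrument_treatment_or(co, "z")
  expect_equal(or$or, (80 * 40) / (20 * 60), tolerance = 1e-6)
  expect_lt(or$ci_low, or$or); expect_gt(or$ci_high, or$or)

  # scaling all counts down 10x widens the CI at the same point estimate
  co_small <- cohort_from_counts(10, 3, 8, 10, 3, 6)
  or_small <- instrument_treatment_or(co_small, "z")
  expect_equal(or_small$or, or$or, tolerance = 1e-6)
  expect_gt(log(or_small$ci_high) - log(or_small$ci_low),
            log(or$ci_high) - log(or$ci_low))

  # independence: OR ~ 1
  co_ind <- cohort_from_counts(200, 60, 120, 200, 60, 120)
  expect_equal(instrument_treatment_or(co_ind, "z")$or, 1, tolerance = 1e-6)
})

test_that("group-rate dichotomization follows the threshold rule", {
  co <- tibble::tibble(
    patient_id = 1:40,
    treatment = c(rep(c(1, 0), c(14, 6)), rep(c(1, 0), c(18, 2))),
    outcome = rep_len(c(0, 1), 40),
    country = rep(c("A", "B"), each = 20) # rates 0.70 and 0.90
  )
  out <- dichotomize_by_group_rate(co, "country", threshold = 0.85)
  expect_equal(unique(out$country_high_rate[out$country == "A"]), 0L)
  expect_equal(unique(out$country_high_rate[out$country == "B"]), 1L)

  # all groups above threshold: constant candidate, flagged degenerate
  expect_warning(dichotomize_by_group_rate(co, "country", threshold = 0.5),
                 "degenerate|constant")

  # even-split helper: the cut that divides patients most evenly
  co2 <- tibble::tibble(
    patient_id = 1:60,
    treatment = c(rep(c(1, 0), c(5, 15)), rep(c(1, 0), c(16, 4)),
                  rep(c(1, 0), c(19, 1))),
    outcome = rep_len(c(0, 1), 60),
    country = rep(c("A", "B", "C"), each = 20) # rates 0.25, 0.80, 0.95
  )
  # cutting at 0.80 gives 40 high / 20 low; cutting at 0.95 gives 20/40;
  # both are equally uneven, the scan returns the smallest such cut
  expect_equal(balanced_rate_threshold(co2, "country"), 0.80)
})

test_that("candidate ranking prefers strong, balanced instruments", {
  co <- simulate_cohort(confounded_config(4000, seed = 71))
  co$noise_iv <- withr::with_seed(72, rbinom(nrow(co), 1, 0.5))
  rep <- suppressWarnings(
    evaluate_instruments(co, c("noise_iv", "z"), c("sev1", "sev2"))
  )
  expect_s3_class(rep, "instrument_report")
  expect_equal(rep$instrument[1], "z") # built-in instrument ranks first
  expect_false(rep$weak[1])
  expect_equal(rep$rank, 1:2)
  # balance stratified by the valid instrument beats stratification by the
  # confounded treatment
  expect_lt(rep$mean_abs_d_by_iv[1], rep$mean_abs_d_by_treatment[1])
})

test_that("a simulated valid instrument outranks pure noise in most replicates", {
  wins <- purrr::map_lgl(1:20, function(s) {
    co <- simulate_cohort(confounded_config(1500, seed = 300 + s))
    co$noise_iv <- withr::with_seed(700 + s, rbinom(nrow(co), 1, 0.5))
    rep <- suppressWarnings(
      evaluate_instruments(co, c("noise_iv", "z"), c("sev1", "sev2"))
    )
    rep$instrument[1] == "z"
  })
  expect_gte(mean(wins), 0.95)
})
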