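test_that("caliper is 0.2 x sample SD of the logit propensity score", {
  # logit-PS values {-1, 0, 1, 2}: sample SD = 1.29099, caliper = 0.258199
  expect_equal(0.2 * sd(c(-1, 0, 1, 2)), 0.2581989, tolerance = 1e-6)

  co <- simulate_cohort(confounded_config(800, seed = 21))
  pf <- fit_propensity(co, c("sev1", "sev2"))
  expect_equal(pf$caliper, 0.2 * sd(pf$logit_ps), tolerance = 1e-12)
  expect_true(all(pf$ps > 0 & pf$ps < 1))
  expect_equal(pf$logit_ps, qlogis(pf$ps), tolerance = 1e-12)
  # PS discriminates the arms in a confounded cohort
  expect_gt(mean(pf$ps[co$treatment == 1]), mean(pf$ps[co$treatment == 0]))
})

test_that("a treatment independent of covariates gives a flat PS and the caliper floor", {
  co <- withr::with_seed(31, tibble::tibble(
    patient_id = 1:400,
    treatment = rep(c(1, 0), c(240, 160)),
    outcome = rbinom(400, 1, 0.3),
    noise = rnorm(400)
  ))
  pf <- fit_propensity(co, "noise")
  expect_equal(mean(pf$ps), 0.6, tolerance = 1e-3)
  expect_lt(sd(pf$ps), 0.05) # near-flat: covariate carries no signal
  expect_equal(pf$caliper, max(0.2 * sd(pf$logit_ps), 1e-6)) # incl. the floor
})

test_that("tiny matching instances behave exactly", {
  mk <- function(lp, trt) {
    co <- tibble::tibble(patient_id = seq_along(lp), treatment = trt,
                         outcome = rep_len(c(0, 1), length(lp)))
    pf <- structure(list(model = NULL, ps = plogis(lp), logit_ps = lp,
                         caliper = 0.26, covariate_names = character(),
                         patient_id = co$patient_id),
                    class = "propensity_fit")
    list(co = co, pf = pf)
  }
  # one treated at 0.0, one control at 0.1, caliper 0.26: exactly one pair
  d <- mk(c(0, 0.1), c(1, 0))
  m <- match_without_replacement(d$pf, d$co, seed = 1)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$treated_id, 1)
  expect_equal(m$pairs$control_id, 2)
  expect_equal(m$n_unmatched_treated, 0)
  expect_equal(m$n_unmatched_control, 0)

  # every control outside the caliper: zero pairs, all unmatched
  d <- mk(c(0, 1, 5, 6), c(1, 1, 0, 0))
  m <- match_without_replacement(d$pf, d$co, seed = 1)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$n_unmatched_treated, 2)
  expect_equal(m$n_unmatched_control, 2)
})

test_that("greedy matching equals an exhaustive greedy-order oracle", {
  # 3 treated vs 2 controls with enumerable distances; the matcher must
  # reproduce plain greedy matching run in its seeded processing order
  greedy_oracle <- function(order_min, min_lp, maj_lp, maj_ids, caliper) {
    used <- logical(length(maj_lp))
    pairs <- list()
    for (i in order_min) {
      avail <- which(!used)
      if (!length(avail)) break
      dd <- abs(maj_lp[avail] - min_lp[i])
      if (min(dd) > caliper) next
      cand <- avail[dd == min(dd)]
      j <- cand[which.min(maj_ids[cand])]
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
    pairs
  }
  lp <- c(0.00, 0.10, 0.50, 0.05, 0.12) # treated: 1-3, controls: 4-5
  trt <- c(1, 1, 1, 0, 0)
  co <- tibble::tibble(patient_id = 1:5, treatment = trt, outcome = c(0, 1, 0, 1, 0))
  pf <- structure(list(model = NULL, ps = plogis(lp), logit_ps = lp,
                       caliper = 0.2, covariate_names = character(),
                       patient_id = co$patient_id),
                  class = "propensity_fit")
  min_idx <- which(trt == 0) # controls are the minority arm
  for (seed in 1:12) {
    m <- match_without_replacement(pf, co, seed = seed)
    order_min <- withr::with_seed(seed, sample(min_idx))
    oracle <- greedy_oracle(match(order_min, min_idx),
                            lp[min_idx], lp[trt == 1], co$patient_id[trt == 1],
                            caliper = 0.2)
    oracle_pairs <- tibble::tibble(
      treated_id = purrr::map_int(oracle, ~ co$patient_id[trt == 1][.x[2]]),
      control_id = purrr::map_int(oracle, ~ co$patient_id[min_idx][.x[1]])
    )
    got <- m$pairs[order(m$pairs$control_id), c("treated_id", "control_id")]
    want <- oracle_pairs[order(oracle_pairs$control_id), ]
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("matching invariants hold on a simulated cohort", {
  co <- simulate_cohort(confounded_config(1200, seed = 41))
  pf <- fit_propensity(co, c("sev1", "sev2"))
  m <- match_without_replacement(pf, co, seed = 5)
  ids <- c(m$pairs$treated_id, m$pairs$control_id)
  expect_false(anyDuplicated(ids) > 0) # no reuse
  lp <- setNames(pf$logit_ps, co$patient_id)
  expect_true(all(abs(lp[as.character(m$pairs$treated_id)] -
                        lp[as.character(m$pairs$control_id)]) <=
                    m$caliper_used + 1e-12))
  expect_lte(nrow(m$pairs), min(sum(co$treatment), sum(1 - co$treatment)))

  # pair count is monotone non-decreasing in the caliper
  calipers <- c(0.01, 0.05, 0.1, 0.5, 1)
  counts <- purrr::map_int(calipers, function(cal) {
    nrow(match_without_replacement(pf, co, seed = 5, caliper = cal)$pairs)
  })
  expect_true(all(diff(counts) >= 0))

  # identical logit-PS multisets in both arms: every minority patient matches
  co2 <- tibble::tibble(patient_id = 1:20,
                        treatment = rep(c(1, 0), each = 10),
                        outcome = rep_len(c(0, 1), 20))
  pf2 <- structure(list(model = NULL, ps = plogis(rep(seq(-1, 1, length.out = 10), 2)),
                        logit_ps = rep(seq(-1, 1, length.out = 10), 2),
                        caliper = 0.3, covariate_names = character(),
                        patient_id = co2$patient_id),
                   class = "propensity_fit")
  m2 <- match_without_replacement(pf2, co2, seed = 9)
  expect_equal(nrow(m2$pairs), 10)
  expect_equal(max(m2$pairs$distance), 0)
})

test_that("matched_effect recovers closed-form proportions", {
  # matched arms with event rates 0.30 vs 0.25 (n = 200 each)
  co <- tibble::tibble(
    patient_id = 1:400,
    treatment = rep(c(1, 0), each = 200),
    outcome = c(rep(c(1, 0), c(60, 140)), rep(c(1, 0), c(50, 150)))
  )
  m <- structure(list(pairs = tibble::tibble(treated_id = 1:200,
                                             control_id = 201:400,
                                             distance = 0),
                      caliper_used = 0.1, n_unmatched_treated = 0,
                      n_unmatched_control = 0),
                 class = "matched_cohort")
  rd <- matched_effect(co, m, "RD")
  expect_one_row_estimate(rd, "ps_matched", "RD")
  expect_equal(rd$point, 0.05, tolerance = 1e-12)
  or <- matched_effect(co, m, "OR")
  expect_equal(or$point, (0.30 / 0.70) / (0.25 / 0.75), tolerance = 1e-6)

  # identical event rates: OR = 1, RD = 0
  co_eq <- dplyr::mutate(co, outcome = rep(rep(c(1, 0), c(50, 150)), 2))
  expect_equal(matched_effect(co_eq, m, "RD")$point, 0, tolerance = 1e-12)
  expect_equal(matched_effect(co_eq, m, "OR")$point, 1, tolerance = 1e-8)
})

test_that("balance tables compute pooled-SD standardized differences", {
  expect_equal(standardized_difference(c(0, 1, 2), c(-1, 0, 1)), 1.0) # SDs 1, means 1 and 0
  expect_equal(standardized_difference(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_true(is.na(standardized_difference(c(1, 1), c(0, 0))))
  expect_equal(
    standardized_difference(rep(c(1, 0), c(60, 40)), rep(c(1, 0), c(50, 50)),
                            kind = "binary"),
    0.1 / sqrt((0.24 + 0.25) / 2), tolerance = 1e-7
  )

  # identical groups: all d = 0
  co <- tibble::tibble(patient_id = 1:40, treatment = rep(c(1, 0), each = 20),
                       outcome = rep_len(c(0, 1), 40),
                       a = rep(rnorm(20), 2), b = rep(rbinom(20, 1, 0.5), 2))
  bt <- balance_table(co, c("a", "b"))
  expect_equal(bt$d, c(0, 0), tolerance = 1e-12)

  # zero-variance covariate: reported NA, excluded from the mean
  co$c <- c(rep(1, 20), rep(0, 20))
  co$d0 <- 5
  bt <- balance_table(co, c("a", "c", "d0"))
  expect_true(is.na(bt$d[bt$covariate == "c"])) # both-arm variance zero
  expect_equal(attr(bt, "mean_abs_d"), mean(abs(bt$d), na.rm = TRUE))
})

test_that("matching reduces covariate imbalance in confounded cohorts", {
  co <- simulate_cohort(confounded_config(2500, seed = 55))
  covs <- c("sev1", "sev2")
  pre <- balance_table(co, covs)
  pf <- fit_propensity(co, covs)
  m <- match_without_replacement(pf, co, seed = 3)
  post <- balance_table(co, covs, ids = matched_ids(m))
  expect_lt(attr(post, "mean_abs_d"), attr(pre, "mean_abs_d"))
})
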