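test_that("allocation and structure match the configuration", {
  cfg <- trial_config(seed = 1)
  ds <- generate_trial(cfg)
  p <- ds$participants
  expect_equal(nrow(p), 334)
  expect_equal(sum(p$arm == "intervention"), 167)
  expect_equal(sum(p$arm == "control"), 167)
  expect_true(all(p$sessions_attended[p$arm == "control"] == 0))
  expect_true(all(p$sessions_attended[p$arm == "intervention"] >= 2 &
                    p$sessions_attended[p$arm == "intervention"] <= 23))
  sdq <- as.matrix(p[c("sdq_0", "sdq_6", "sdq_12")])
  expect_true(all(sdq == round(sdq) & sdq >= 0 & sdq <= 40))
  u <- as.matrix(p[grep("^utility_", names(p))])
  expect_true(all(u >= 0 & u <= 1))
})

test_that("generation is byte-identical for identical configs", {
  a <- generate_trial(trial_config(seed = 7))
  b <- generate_trial(trial_config(seed = 7))
  expect_identical(a, b)
  c <- generate_trial(trial_config(seed = 8))
  expect_false(identical(a$participants$cost_baseline,
                         c$participants$cost_baseline))
})

test_that("configuration errors name the offending field", {
  expect_error(trial_config(allocation = c(intervention = 100, control = 100)),
               "allocation", class = "trialcea_config_error")
  expect_error(trial_config(missingness = list(sdq = c(m6 = 1.2, m12 = 0.2))),
               "missingness")
  expect_error(trial_config(session_mean = 50), "session_mean")
  expect_error(trial_config(utility_means = list(cyp = c(0.5, 0.5, 1.4),
                                                 caregiver = c(0.5, 0.5, 0.5))),
               "utility_means")
})

test_that("zero effect with vanishing noise gives equal arm means", {
  cfg <- small_config(n = 200, seed = 3,
                      effect_sdq_12m = 0, effect_sdq_6m = 0,
                      sdq_between_sd = 1e-8, sdq_within_sd = 1e-8,
                      sdq_trend_control = c(19, 19),
                      sdq_mean_baseline = 19,
                      site_sd = list(cost = 300, sdq = 1e-8, utility = 0.02))
  p <- generate_trial(cfg)$participants
  expect_equal(mean(p$sdq_12[p$arm == "intervention"]),
               mean(p$sdq_12[p$arm == "control"]))
})

test_that("period costs are right-skewed and nonnegative", {
  p <- generate_trial(trial_config(seed = 11))$participants
  for (col in c("cost_baseline", "cost_0_6", "cost_6_12")) {
    expect_true(all(p[[col]] >= 0))
    expect_gt(sample_skewness(p[[col]]), 0)
  }
})

test_that("stored costs equal re-priced service use exactly", {
  ds <- generate_trial(trial_config(seed = 5))
  before <- ds$participants[c("cost_baseline", "cost_0_6", "cost_6_12",
                              "cost_intervention", "cost_total")]
  session_price <- ds$config$cost_per_session /
    cost_intervention_session(intervention_cost_model())$total
  # re-cost with a model priced at the generator's per-session rate
  m <- intervention_cost_model()
  recost <- cost_trial(ds, model = m)
  expect_equal(recost$participants$cost_baseline, before$cost_baseline)
  expect_equal(recost$participants$cost_0_6, before$cost_0_6)
  expect_equal(recost$participants$cost_6_12, before$cost_6_12)
  # intervention component agrees up to the per-session price ratio
  expect_equal(recost$participants$cost_intervention * session_price,
               before$cost_intervention, tolerance = 1e-10)
})

test_that("zero missingness rates leave the dataset unchanged", {
  cfg <- small_config(seed = 9, missingness = list(
    sdq = c(m6 = 0, m12 = 0), cost = c(m6 = 0, m12 = 0),
    utility_cyp = c(m6 = 0, m12 = 0), utility_caregiver = c(m6 = 0, m12 = 0)))
  ds <- generate_trial(cfg)
  expect_identical(apply_missingness(ds, cfg), ds)
})

test_that("masked fractions match configured rates within binomial error", {
  cfg <- trial_config(seed = 21)
  ds <- apply_missingness(add_qalys(generate_trial(cfg)), cfg)
  p <- ds$participants
  n <- nrow(p)
  check_rate <- function(col, rate) {
    k <- sum(is.na(p[[col]]))
    expect_lt(abs(k - n * rate), 3 * sqrt(n * rate * (1 - rate)) + 1e-9)
  }
  check_rate("sdq_12", 0.22)
  check_rate("sdq_6", 0.16)
  check_rate("cost_6_12", 0.22)
  check_rate("utility_cyp_12", 0.35)
  check_rate("utility_caregiver_6", 0.20)
  # monotone within measure: missing at 6 months implies missing at 12
  expect_true(all(is.na(p$sdq_12[is.na(p$sdq_6)])))
  expect_true(all(is.na(p$utility_cyp_12[is.na(p$utility_cyp_6)])))
  # baseline is never masked
  expect_false(anyNA(p$sdq_0))
  expect_false(anyNA(p$cost_baseline))
  # QALYs go missing iff a constituent utility is missing
  expect_equal(is.na(p$qaly_cyp),
               is.na(p$utility_cyp_6) | is.na(p$utility_cyp_12))
  # MAR masking is deterministic given the seed
  expect_identical(apply_missingness(add_qalys(generate_trial(cfg)), cfg), ds)
})

test_that("MAR masking is linked to baseline severity and cost", {
  cfg <- trial_config(seed = 31, mar_coef = c(sdq = 1.5, log_cost = 0))
  p <- apply_missingness(generate_trial(cfg), cfg)$participants
  expect_gt(mean(p$sdq_0[is.na(p$sdq_12)]), mean(p$sdq_0[!is.na(p$sdq_12)]))
})

test_that("complete-case estimates are unbiased under MCAR masking", {
  R <- 60
  truth <- -2.021
  set.seed(100)
  seeds <- sample.int(2^31 - 2, R)
  est <- vapply(seq_len(R), function(i) {
    cfg <- trial_config(seed = seeds[i], missingness_mechanism = "MCAR")
    ds <- apply_missingness(generate_trial(cfg), cfg)
    adjusted_difference(ds, default_adjustment_spec("sdq_12"))$estimate
  }, numeric(1))
  mc_se <- sd(est) / sqrt(R)
  expect_lt(abs(mean(est) - truth), 3 * mc_se)
})
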