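masked_dataset <- function(n = 334, seed = 51, mechanism = "MAR") {
  cfg <- trial_config(n_participants = n,
                      allocation = c(intervention = n / 2, control = n / 2),
                      missingness_mechanism = mechanism, seed = seed)
  apply_missingness(add_qalys(cost_trial(generate_trial(cfg))), cfg)
}

test_that("a complete dataset imputes to identical copies", {
  ds <- small_dataset(seed = 61)
  out <- impute_chained(ds, imputation_config(m_imputations = 3, seed = 1))
  expect_length(out, 3)
  for (o in out) expect_identical(o$participants, ds$participants)
})

test_that("PMM with one donor returns the nearest-prediction donor value", {
  # a perfect linear relation: the parameter draw collapses onto the fit,
  # so the missing case at x = 30 must borrow the donor at x = 10
  dat <- tibble::tibble(x = c(1:10, 30), y = c(2 * (1:10), NA))
  set.seed(2)
  imp <- trialcea:::pmm_draw(dat, "y", "x", mis = is.na(dat$y), k = 1)
  expect_equal(imp, 20)
})

test_that("imputed values lie in the observed support of each variable", {
  ds <- masked_dataset(n = 200, seed = 71)
  out <- impute_chained(ds, imputation_config(m_imputations = 3,
                                              iterations = 3, seed = 5))
  for (v in c("cost_0_6", "sdq_12", "qaly_cyp")) {
    obs <- ds$participants[[v]][!is.na(ds$participants[[v]])]
    for (o in out) {
      expect_false(anyNA(o$participants[[v]]))
      expect_true(all(o$participants[[v]] %in% obs))
    }
  }
  # derived totals are recomputed from imputed constituents
  p1 <- out[[1]]$participants
  expect_equal(p1$cost_total, p1$cost_0_6 + p1$cost_6_12 +
                 p1$cost_intervention)
  expect_equal(p1$qaly_combined, p1$qaly_cyp + p1$qaly_caregiver)
})

test_that("the chain is deterministic given its seed", {
  ds <- masked_dataset(n = 150, seed = 81)
  cfg <- imputation_config(m_imputations = 2, iterations = 2, seed = 9)
  a <- impute_chained(ds, cfg)
  b <- impute_chained(ds, cfg)
  expect_identical(lapply(a, `[[`, "participants"),
                   lapply(b, `[[`, "participants"))
})

test_that("too few donors is an error", {
  ds <- small_dataset(seed = 91)
  ds$participants$sdq_12[-(1:3)] <- NA
  expect_error(impute_chained(ds, imputation_config(m_imputations = 2,
                                                    donors_k = 5)),
               "donors_k")
})

test_that("Rubin's rules reproduce hand computation and the identity", {
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$q_bar, 2)
  expect_equal(p$w_bar, 1)
  expect_equal(p$b_var, 2)
  expect_equal(p$total_var, 4)

  # degenerate: identical estimates collapse the between component
  p0 <- pool_rubin(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(p0$b_var, 0)
  expect_equal(p0$total_var, p0$w_bar)
  expect_equal(p0$df, Inf)

  set.seed(3)
  for (i in 1:20) {
    m <- sample(2:20, 1)
    est <- rnorm(m)
    v <- runif(m, 0.1, 2)
    pr <- pool_rubin(est, v)
    expect_identical(pr$total_var, pr$w_bar + (1 + 1 / m) * pr$b_var)
  }
  expect_error(pool_rubin(1, 2), "m >= 2")
  expect_error(pool_rubin(c(1, 2), c(1, 1, 1)), "equal length")
})

test_that("pooling m fits of one complete dataset returns the single fit", {
  ds <- small_dataset(seed = 95)
  spec <- default_adjustment_spec("sdq_12", estimator = "ols_fallback")
  single <- adjusted_difference(ds, spec)
  pooled <- pooled_difference(impute_chained(
    ds, imputation_config(m_imputations = 3, seed = 1)), spec)
  expect_equal(pooled$q_bar, single$estimate)
  expect_equal(pooled$b_var, 0)
})

test_that("pooled PMM estimates track the truth with nominal coverage under MCAR", {
  # Predictive mean matching attenuates regression coefficients slightly
  # toward zero (donor mixing across arms); an independent reference
  # implementation shows the same, larger, shrinkage on an analogous
  # problem. The honest property is therefore small relative bias of the
  # pooled estimate, not exact unbiasedness at Monte-Carlo resolution.
  R <- 200
  truth <- -2.021
  spec <- default_adjustment_spec("sdq_12", estimator = "ols_fallback")
  set.seed(202)
  seeds <- sample.int(2^31 - 2, R)
  est <- cover <- numeric(R)
  for (i in seq_len(R)) {
    ds <- masked_dataset(seed = seeds[i], mechanism = "MCAR")
    icfg <- imputation_config(m_imputations = 5, iterations = 5,
                              seed = seeds[i])
    pooled <- pooled_difference(impute_chained(ds, icfg), spec)
    est[i] <- pooled$q_bar
    cover[i] <- pooled$ci_low <= truth && truth <= pooled$ci_high
  }
  mc_se <- sd(est) / sqrt(R)
  # relative bias under 10% of the effect, and any shrinkage points toward 0
  expect_lt(abs(mean(est) - truth), 0.10 * abs(truth))
  expect_lt(abs(mean(est)), abs(truth) + 3 * mc_se)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("CEAC under MI on identical complete datasets matches single-data CEAC", {
  ds <- small_dataset(n = 150, seed = 103)
  copies <- impute_chained(ds, imputation_config(m_imputations = 4, seed = 1))
  cs <- default_adjustment_spec("cost_total", estimator = "ols_fallback")
  es <- default_adjustment_spec("qaly_combined", estimator = "ols_fallback")
  grid <- wtp_grid(seq(0, 50000, 10000))
  B <- 240
  mi <- ceac_under_mi(copies, cs, es, grid, B = B, seed = 11)
  single <- ceac(bootstrap_incrementals(ds, cs, es, B = B, seed = 17), grid)
  for (j in seq_along(grid$values)) {
    p <- single$curve$probability[j]
    se <- sqrt(max(p * (1 - p), 0.25 / B) / B)
    expect_lt(abs(mi$curve$probability[j] - p), 4 * se + 1e-9)
  }
  expect_error(ceac_under_mi(copies, cs, es, grid, B = 3, seed = 1),
               "at least the number")
})

test_that("MI CEAC agrees with the complete-data oracle under MCAR", {
  cfg <- trial_config(n_participants = 334,
                      allocation = c(intervention = 167, control = 167),
                      missingness_mechanism = "MCAR", seed = 113)
  full <- add_qalys(cost_trial(generate_trial(cfg)))
  masked <- apply_missingness(full, cfg)
  cs <- default_adjustment_spec("cost_total", estimator = "ols_fallback")
  es <- default_adjustment_spec("qaly_combined", estimator = "ols_fallback")
  grid <- wtp_grid(seq(0, 50000, 10000))
  B <- 200
  oracle <- ceac(bootstrap_incrementals(full, cs, es, B = B, seed = 7), grid)
  mi <- ceac_under_mi(impute_chained(masked,
                                     imputation_config(m_imputations = 5,
                                                       iterations = 5,
                                                       seed = 7)),
                      cs, es, grid, B = B, seed = 7)
  for (j in seq_along(grid$values)) {
    p <- oracle$curve$probability[j]
    se <- sqrt(max(p * (1 - p), 0.25 / B) / B)
    # MI adds imputation noise on top of two independent Monte-Carlo runs
    expect_lt(abs(mi$curve$probability[j] - p), 6 * se + 0.05)
  }
})

test_that("the Rubin-NMB engine gives a probability curve in bounds", {
  ds <- masked_dataset(n = 150, seed = 121)
  copies <- impute_chained(ds, imputation_config(m_imputations = 3,
                                                 iterations = 3, seed = 2))
  cs <- default_adjustment_spec("cost_total", estimator = "ols_fallback")
  es <- default_adjustment_spec("qaly_cyp", estimator = "ols_fallback")
  cc <- ceac_under_mi(copies, cs, es, wtp_grid(seq(0, 40000, 10000)),
                      seed = 3, method = "rubin_nmb")
  expect_true(all(cc$curve$probability >= 0 & cc$curve$probability <= 1))
  expect_equal(cc$method, "rubin_nmb")
})
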