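test_that("ICER arithmetic and quadrant labels", {
  r <- icer(100, 0.05)
  expect_equal(r$ratio, 2000)
  expect_equal(r$quadrant, "trade-off NE")
  expect_equal(icer(-100, 0.05)$quadrant, "dominant SE")
  expect_equal(icer(100, -0.05)$quadrant, "dominated NW")
  expect_equal(icer(-100, -0.05)$quadrant, "trade-off SW")
  z <- icer(50, 0)
  expect_true(is.nan(z$ratio))
  expect_match(z$quadrant, "added cost")
})

test_that("net monetary benefit arithmetic", {
  expect_equal(net_monetary_benefit(0.7, 5000, 20000), 9000)
  expect_equal(net_monetary_benefit(0.7, 5000, 0), -5000)
  expect_equal(net_monetary_benefit(0, 0, 30000), 0)
})

test_that("willingness-to-pay grids validate their contract", {
  expect_error(wtp_grid(c(10, 5)), "increasing")
  expect_error(wtp_grid(c(-1, 5)), "increasing|nonnegative")
  g <- default_wtp_grid("sdq")
  expect_equal(range(g$values), c(0, 1000))
  expect_equal(default_wtp_grid("qaly")$values[2] -
                 default_wtp_grid("qaly")$values[1], 500)
})

make_dist <- function(dc, de) {
  structure(list(replicates = tibble::tibble(delta_cost = dc,
                                             delta_effect = de),
                 B = length(dc), seed = 0L, n_redrawn = 0L,
                 effect_label = "toy",
                 point = c(delta_cost = mean(dc), delta_effect = mean(de))),
            class = "incremental_distribution")
}

test_that("CEAC probabilities match brute-force counting", {
  d <- make_dist(c(10, 20, 30, 40), c(1, 1, -1, 1))
  cc <- ceac(d, wtp_grid(c(0, 25, 100), "toy"))
  # lambda 25: net benefits {15, 5, -55, -15} -> 2 of 4 positive
  expect_equal(cc$curve$probability[cc$curve$wtp == 25], 0.5)
  # lambda 0: probability = fraction of cost-saving replicates
  expect_equal(cc$curve$probability[cc$curve$wtp == 0], 0)
  d2 <- make_dist(c(-10, 5), c(1, 1))
  expect_equal(ceac(d2, wtp_grid(c(0)))$curve$probability, 0.5)
  # ties at exactly zero net benefit count as one half
  d3 <- make_dist(c(10, 50), c(1, 1))
  expect_equal(ceac(d3, wtp_grid(c(10)))$curve$probability, 0.5 * 0.5)
})

test_that("dominant replicates give probability one everywhere", {
  d <- make_dist(rep(-5, 10), rep(0.2, 10))
  cc <- ceac(d, default_wtp_grid("qaly"))
  expect_true(all(cc$curve$probability == 1))
  expect_equal(cc$crossing_lambda, 0)
})

test_that("CEAC is monotone when all incremental effects share a sign", {
  set.seed(4)
  d_pos <- make_dist(rnorm(200, 100, 50), abs(rnorm(200, 0.05, 0.02)) + 1e-6)
  p <- ceac(d_pos, default_wtp_grid("qaly"))$curve$probability
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  d_neg <- make_dist(rnorm(200, 100, 50), -abs(rnorm(200, 0.05, 0.02)) - 1e-6)
  p2 <- ceac(d_neg, default_wtp_grid("qaly"))$curve$probability
  expect_true(all(diff(p2) <= 0))
})

test_that("identity resampling reproduces the point estimates", {
  ds <- small_dataset(seed = 13)
  d <- bootstrap_incrementals(
    ds, default_adjustment_spec("cost_total"),
    default_adjustment_spec("qaly_cyp"), B = 1, seed = 1,
    .resampler = function(df) seq_len(nrow(df)))
  expect_equal(d$replicates$delta_cost, d$point[["delta_cost"]])
  expect_equal(d$replicates$delta_effect, d$point[["delta_effect"]])
})

test_that("bootstrap is deterministic given the seed", {
  ds <- small_dataset(seed = 19)
  cs <- default_adjustment_spec("cost_total", estimator = "ols_fallback")
  es <- default_adjustment_spec("qaly_cyp", estimator = "ols_fallback")
  a <- bootstrap_incrementals(ds, cs, es, B = 25, seed = 5)
  b <- bootstrap_incrementals(ds, cs, es, B = 25, seed = 5)
  expect_identical(a$replicates, b$replicates)
  c <- bootstrap_incrementals(ds, cs, es, B = 25, seed = 6)
  expect_false(identical(a$replicates, c$replicates))
})

test_that("bootstrap frequencies match exhaustive enumeration on a toy set", {
  df <- toy4()
  # enumerate all 4 x 4 equally likely within-arm resamples
  combos <- expand.grid(c1 = 1:2, c2 = 1:2, t1 = 3:4, t2 = 3:4)
  exact <- t(apply(combos, 1, function(ix) {
    c(dc = mean(df$cost[ix[3:4]]) - mean(df$cost[ix[1:2]]),
      de = mean(df$eff[ix[3:4]]) - mean(df$eff[ix[1:2]]))
  }))
  key <- function(dc, de) paste(round(dc, 8), round(de, 8))
  exact_tab <- table(key(exact[, 1], exact[, 2])) / nrow(exact)

  B <- 4000
  d <- bootstrap_incrementals(df, bare_spec("cost"), bare_spec("eff"),
                              B = B, seed = 3)
  got <- table(factor(key(d$replicates$delta_cost, d$replicates$delta_effect),
                      levels = names(exact_tab))) / B
  for (k in names(exact_tab)) {
    p <- exact_tab[[k]]
    expect_lt(abs(got[[k]] - p), 3 * sqrt(p * (1 - p) / B))
  }
})

test_that("bootstrap mean tracks the point estimate on calibrated data", {
  ds <- small_dataset(n = 200, seed = 37)
  d <- bootstrap_incrementals(
    ds, default_adjustment_spec("cost_total", estimator = "ols_fallback"),
    default_adjustment_spec("qaly_cyp", estimator = "ols_fallback"),
    B = 300, seed = 2)
  se <- sd(d$replicates$delta_effect) / sqrt(300)
  expect_lt(abs(mean(d$replicates$delta_effect) - d$point[["delta_effect"]]),
            5 * se)
})

test_that("degenerate resamples trigger the redraw guard", {
  df <- toy4()
  only_control <- function(d) c(1, 2, 1, 2)
  expect_error(
    bootstrap_incrementals(df, bare_spec("cost"), bare_spec("eff"),
                           B = 50, seed = 1, .resampler = only_control),
    "degenerate")
})

test_that("scenario runner covers tokens, bounds and cost monotonicity", {
  ds <- small_dataset(n = 120, seed = 41)
  sc <- scenario_grid(outcome = "sdq_12m", data = "complete_case",
                      costing = c("full", "s75"))
  res <- run_scenarios(ds, sc, B = 80, seed = 9,
                       estimator = "ols_fallback")
  expect_equal(nrow(res), 2)
  p_full <- res$ceac[[which(res$costing == "full")]]$curve$probability
  p_s75 <- res$ceac[[which(res$costing == "s75")]]$curve$probability
  expect_true(all(p_full >= 0 & p_full <= 1))
  # cheaper intervention can never look less cost-effective, per replicate
  expect_true(all(p_s75 >= p_full))
  cl_full <- res$crossing_lambda[res$costing == "full"]
  cl_s75 <- res$crossing_lambda[res$costing == "s75"]
  if (!is.na(cl_full) && !is.na(cl_s75)) expect_lte(cl_s75, cl_full)

  one <- run_scenarios(ds, scenario_grid(outcome = "qaly_cyp"), B = 40,
                       seed = 9, estimator = "ols_fallback")
  expect_equal(nrow(one), 1)
  expect_error(run_scenarios(ds, scenario_grid(outcome = "banana"), B = 10),
               "unknown scenario")
})
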