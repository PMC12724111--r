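#' Generate a synthetic two-arm trial dataset
#'
#' Simulates a participant-level dataset with the statistical structure a
#' within-trial economic evaluation assumes: 1:1 permuted allocation across
#' sites, four categorical minimisation factors, right-skewed gamma costs
#' with configurable baseline imbalance, latent-normal utility trajectories
#' clipped to the admissible range, integer SDQ scores in `[0, 40]`, and
#' per-participant intervention session counts. All configured treatment
#' effects are conditional effects given baseline covariates, so the adjusted
#' estimators are calibrated to recover them in expectation.
#'
#' Service use is generated cost-first: a target cost is drawn for each
#' participant-period from the calibrated gamma model, decomposed into
#' per-category quantities (Dirichlet-perturbed expected shares divided by
#' unit costs, rounded to integer counts), and the stored period cost is the
#' re-priced quantity total. Pricing the emitted service-use records with the
#' same unit-cost table therefore reproduces the stored costs exactly.
#'
#' @param config A [trial_config()].
#' @param unit_costs A [unit_cost_table()] used to decompose period costs
#'   into service-use quantities; defaults to the bundled synthetic table.
#' @return A `trial_dataset`: a list with `participants` (one row per
#'   participant, wide), `service_use` (long records with positive
#'   quantities), and the generating `config`. Generation is byte-identical
#'   for identical configs.
#' @examples
#' ds <- generate_trial(trial_config(n_participants = 60,
#'   allocation = c(intervention = 30, control = 30), seed = 7))
#' table(ds$participants$arm)
#' @export
generate_trial <- function(config, unit_costs = default_unit_costs()) {
  if (!inherits(config, "trial_config"))
    abort_config("`config` must be a trial_config object", "config")
  set.seed(config$seed)
  n <- config$n_participants
  alloc <- config$allocation

  arm <- factor(sample(rep(c("control", "intervention"),
                           c(alloc[["control"]], alloc[["intervention"]]))),
                levels = c("control", "intervention"))
  treat <- as.numeric(arm == "intervention")
  site_id <- factor(sample.int(config$n_sites, n, replace = TRUE),
                    levels = seq_len(config$n_sites))

  disorder <- factor(sample(c("anxiety", "depression", "disruptive"), n,
                            replace = TRUE, prob = c(0.50, 0.20, 0.30)),
                     levels = c("anxiety", "depression", "disruptive"))
  asd <- factor(sample(c("no", "yes"), n, TRUE, prob = c(0.60, 0.40)),
                levels = c("no", "yes"))
  age_group <- factor(sample(c("<11", ">=11"), n, TRUE, prob = c(0.55, 0.45)),
                      levels = c("<11", ">=11"))
  intellectual_disability <- factor(sample(c("no", "yes"), n, TRUE,
                                           prob = c(0.60, 0.40)),
                                    levels = c("no", "yes"))

  site_cost <- rnorm(config$n_sites, 0, config$site_sd$cost)
  site_sdq <- rnorm(config$n_sites, 0, config$site_sd$sdq)
  site_util <- rnorm(config$n_sites, 0, config$site_sd$utility)
  isite <- as.integer(site_id)

  # --- costs: baseline (3m) target, decomposed to services, then re-priced
  bl_target <- rgamma(n, shape = config$cost_shape,
                      scale = config$baseline_cost_mean[ifelse(treat == 1,
                        "intervention", "control")] / config$cost_shape)
  bl_decomp <- decompose_cost(bl_target, unit_costs)
  cost_baseline <- bl_decomp$priced

  # follow-up conditional mean is linear in the *priced* baseline cost,
  # which is exactly the covariate the adjusted models condition on
  center <- sum(config$baseline_cost_mean * alloc[c("intervention", "control")] /
                  sum(alloc))
  mu_fu <- config$followup_cost_mean_control +
    config$baseline_cost_coef * (cost_baseline - center) +
    config$effect_cost_excl_intervention * treat +
    site_cost[isite]
  mu_fu <- pmax(mu_fu, 200)
  fu1_target <- rgamma(n, shape = config$cost_shape,
                       scale = (mu_fu / 2) / config$cost_shape)
  fu2_target <- rgamma(n, shape = config$cost_shape,
                       scale = (mu_fu / 2) / config$cost_shape)
  fu1 <- decompose_cost(fu1_target, unit_costs)
  fu2 <- decompose_cost(fu2_target, unit_costs)

  # --- SDQ: participant intercept + occasion noise, additive arm effect,
  # rounded to integer and clamped to the instrument range
  b_sdq <- rnorm(n, 0, config$sdq_between_sd)
  sdq_means <- c(config$sdq_mean_baseline, config$sdq_trend_control)
  sdq_eff <- c(0, config$effect_sdq_6m, config$effect_sdq_12m)
  sdq <- sapply(1:3, function(k) {
    raw <- sdq_means[k] + sdq_eff[k] * treat + b_sdq + site_sdq[isite] +
      rnorm(n, 0, config$sdq_within_sd)
    pmin(pmax(round(raw), 0L), 40L)
  })

  # --- utilities: latent normal, clipped; the arm effect is spread equally
  # over months 6 and 12 and scaled by 1/0.75 so the trapezoid QALY
  # contrast equals the configured QALY effect
  gen_util <- function(means, effect) {
    b <- rnorm(n, 0, config$utility_between_sd)
    delta <- c(0, effect / 0.75, effect / 0.75)
    sapply(1:3, function(k) {
      raw <- means[k] + delta[k] * treat + b + site_util[isite] +
        rnorm(n, 0, config$utility_within_sd)
      pmin(pmax(raw, config$utility_range[1]), config$utility_range[2])
    })
  }
  u_cyp <- gen_util(config$utility_means$cyp, config$effect_qaly_cyp)
  u_cg <- gen_util(config$utility_means$caregiver, config$effect_qaly_caregiver)

  # --- intervention exposure
  probs <- session_count_probs(config$session_range, config$session_mean)
  sessions <- ifelse(treat == 1,
                     sample(as.integer(names(probs)), n, TRUE, prob = probs),
                     0L)
  cost_intervention <- sessions * config$cost_per_session

  participant_id <- sprintf("P%04d", seq_len(n))
  participants <- tibble::tibble(
    participant_id = participant_id,
    arm = arm, site_id = site_id,
    disorder = disorder, asd = asd, age_group = age_group,
    intellectual_disability = intellectual_disability,
    sessions_attended = as.integer(sessions),
    sdq_0 = as.integer(sdq[, 1]), sdq_6 = as.integer(sdq[, 2]),
    sdq_12 = as.integer(sdq[, 3]),
    utility_cyp_0 = u_cyp[, 1], utility_cyp_6 = u_cyp[, 2],
    utility_cyp_12 = u_cyp[, 3],
    utility_caregiver_0 = u_cg[, 1], utility_caregiver_6 = u_cg[, 2],
    utility_caregiver_12 = u_cg[, 3],
    cost_baseline = cost_baseline,
    cost_0_6 = fu1$priced, cost_6_12 = fu2$priced,
    cost_intervention = cost_intervention,
    cost_excl_intervention = fu1$priced + fu2$priced,
    cost_total = fu1$priced + fu2$priced + cost_intervention,
    obs_sdq_6 = TRUE, obs_sdq_12 = TRUE,
    obs_cost_6 = TRUE, obs_cost_12 = TRUE,
    obs_utility_cyp_6 = TRUE, obs_utility_cyp_12 = TRUE,
    obs_utility_caregiver_6 = TRUE, obs_utility_caregiver_12 = TRUE
  )

  service_use <- dplyr::bind_rows(
    service_rows(participant_id, "baseline_3m", bl_decomp$quantities),
    service_rows(participant_id, "m0_6", fu1$quantities),
    service_rows(participant_id, "m6_12", fu2$quantities)
  )

  structure(list(participants = participants, service_use = service_use,
                 config = config),
            class = "trial_dataset")
}

# Decompose target costs (vector, one per participant) into integer service
# quantities via Dirichlet-perturbed expected shares; returns quantities
# (matrix participants x categories) and the re-priced totals.
decompose_cost <- function(target, unit_costs, concentration = 30) {
  shares <- generator_cost_shares()
  cats <- intersect(names(shares), unit_costs$entries$category)
  if (!length(cats))
    stop("unit-cost table shares no categories with the generator's share set",
         call. = FALSE)
  shares <- shares[cats] / sum(shares[cats])
  uc <- unit_cost_lookup(unit_costs, cats)
  n <- length(target)
  g <- matrix(rgamma(n * length(cats), shape = rep(shares * concentration,
                                                   each = n)),
              nrow = n)
  w <- g / rowSums(g)
  raw <- sweep(w * target, 2, uc, "/")
  # stochastic rounding: E[quantity] equals the raw count exactly, so the
  # re-priced total is conditionally unbiased for the target at every cost
  # level (deterministic rounding would clip small shares to zero and bleed
  # more cost from low-cost participants than high-cost ones)
  q <- floor(raw) + (matrix(runif(length(raw)), nrow = n) < raw - floor(raw))
  colnames(q) <- cats
  priced <- as.numeric(q %*% uc)
  list(quantities = q, priced = priced)
}

service_rows <- function(ids, period, quantities) {
  df <- tibble::tibble(
    participant_id = rep(ids, ncol(quantities)),
    period = period,
    category = rep(colnames(quantities), each = length(ids)),
    quantity = as.integer(quantities)
  )
  df[df$quantity > 0, ]
}

#' @export
print.trial_dataset <- function(x, ...) {
  p <- x$participants
  cat(sprintf("<trial_dataset> %d participants (%d intervention / %d control), %d sites\n",
              nrow(p), sum(p$arm == "intervention"), sum(p$arm == "control"),
              nlevels(droplevels(p$site_id))))
  cat(sprintf("  service-use records: %d; seed %d\n",
              nrow(x$service_use), x$config$seed))
  obs <- grep("^obs_", names(p), value = TRUE)
  masked <- sum(!as.matrix(p[obs]))
  if (masked > 0) cat(sprintf("  masked follow-up values: %d\n", masked))
  invisible(x)
}

#' Impose follow-up missingness on a generated dataset
#'
#' Masks follow-up measurements (6- and 12-month SDQ, period costs and
#' utilities) according to the configured per-measure rates, leaving baseline
#' always observed. Missingness is monotone within a measure (a participant
#' missing at 6 months is also missing at 12 months when the 12-month rate is
#' at least the 6-month rate). Under `"MCAR"` every participant shares the
#' configured rate; under `"MAR"` the masking probability is logistic in
#' standardised baseline SDQ and standardised `log1p` baseline cost (slopes
#' `config$mar_coef`), with the intercept solved numerically so the average
#' masking probability equals the configured rate. Service-use records for a
#' masked period are removed, and derived cost totals and utilities are set
#' to `NA`.
#'
#' @param dataset A `trial_dataset` with fully observed follow-up.
#' @param config A [trial_config()]; its `missingness`, mechanism, MAR
#'   coefficients and seed are used.
#' @return The masked `trial_dataset`. Deterministic given the config seed.
#' @export
apply_missingness <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!inherits(config, "trial_config"))
    abort_config("`config` must be a trial_config object", "config")
  p <- dataset$participants
  # distinct stream from generation; modulo keeps the seed a valid integer
  set.seed(as.integer((as.numeric(config$seed) + 1000003) %% 2147483647))

  z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  lp_slope <- config$mar_coef[["sdq"]] * z(as.numeric(p$sdq_0)) +
    config$mar_coef[["log_cost"]] * z(log1p(p$cost_baseline))

  draw_mask <- function(rate, already = rep(FALSE, nrow(p))) {
    # conditional extra-masking rate so the marginal rate matches `rate`
    base_rate <- mean(already)
    target <- if (base_rate >= rate) 0 else (rate - base_rate) / (1 - base_rate)
    if (target <= 0) return(already)
    if (target >= 1) return(rep(TRUE, nrow(p)))
    pr <- if (config$missingness_mechanism == "MCAR") {
      rep(target, nrow(p))
    } else {
      lp <- lp_slope[!already]
      a <- uniroot(function(a) mean(plogis(a + lp)) - target,
                   c(-25, 25), tol = 1e-10)$root
      out <- rep(0, nrow(p))
      out[!already] <- plogis(a + lp_slope[!already])
      out
    }
    already | (runif(nrow(p)) < pr)
  }

  measures <- list(
    sdq = list(cols = c(m6 = "sdq_6", m12 = "sdq_12"),
               flags = c(m6 = "obs_sdq_6", m12 = "obs_sdq_12")),
    cost = list(cols = c(m6 = "cost_0_6", m12 = "cost_6_12"),
                flags = c(m6 = "obs_cost_6", m12 = "obs_cost_12")),
    utility_cyp = list(cols = c(m6 = "utility_cyp_6", m12 = "utility_cyp_12"),
                       flags = c(m6 = "obs_utility_cyp_6",
                                 m12 = "obs_utility_cyp_12")),
    utility_caregiver = list(
      cols = c(m6 = "utility_caregiver_6", m12 = "utility_caregiver_12"),
      flags = c(m6 = "obs_utility_caregiver_6",
                m12 = "obs_utility_caregiver_12"))
  )

  drop_periods <- list()
  for (ms in names(measures)) {
    rates <- config$missingness[[ms]]
    if (is.null(rates) || all(rates == 0)) next
    m6 <- draw_mask(rates[["m6"]])
    m12 <- draw_mask(rates[["m12"]], already = m6)
    info <- measures[[ms]]
    p[[info$cols[["m6"]]]][m6] <- NA
    p[[info$cols[["m12"]]]][m12] <- NA
    p[[info$flags[["m6"]]]] <- !m6
    p[[info$flags[["m12"]]]] <- !m12
    if (ms == "cost") {
      drop_periods <- list(m0_6 = p$participant_id[m6],
                           m6_12 = p$participant_id[m12])
    }
  }

  # derived totals become NA when a component is masked
  p$cost_excl_intervention <- p$cost_0_6 + p$cost_6_12
  p$cost_total <- p$cost_excl_intervention + p$cost_intervention
  # recompute any QALY columns added before masking
  qcols <- intersect(c("qaly_cyp", "qaly_caregiver", "qaly_combined"), names(p))
  su <- dataset$service_use
  if (length(drop_periods)) {
    su <- su[!(su$period == "m0_6" &
                 su$participant_id %in% drop_periods$m0_6), ]
    su <- su[!(su$period == "m6_12" &
                 su$participant_id %in% drop_periods$m6_12), ]
  }
  dataset$participants <- p
  dataset$service_use <- su
  if (length(qcols)) dataset <- add_qalys(dataset)
  dataset
}
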