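#' Incremental cost-effectiveness ratio with quadrant classification
#'
#' Divides the incremental cost by the incremental effect and labels the
#' cost-effectiveness-plane quadrant: north-east (more effective, dearer:
#' trade-off), south-east (more effective, cheaper: dominant), north-west
#' (less effective, dearer: dominated), south-west (less effective,
#' cheaper: trade-off). A zero incremental effect yields an undefined ratio
#' (`NaN`) with the sign of the incremental cost retained in the label.
#'
#' @param delta_cost Incremental cost (GBP, intervention minus control).
#' @param delta_effect Incremental effect in effect units, higher = better.
#' @return A list with `ratio`, `quadrant` and the inputs.
#' @examples
#' icer(100, 0.05)  # 2000, trade-off NE
#' @export
icer <- function(delta_cost, delta_effect) {
  quadrant <- if (delta_effect > 0 && delta_cost >= 0) "trade-off NE"
  else if (delta_effect > 0) "dominant SE"
  else if (delta_effect < 0 && delta_cost >= 0) "dominated NW"
  else if (delta_effect < 0) "trade-off SW"
  else if (delta_cost > 0) "undefined (zero effect, added cost)"
  else if (delta_cost < 0) "undefined (zero effect, cost saving)"
  else "undefined (zero effect, zero cost)"
  ratio <- if (delta_effect == 0) NaN else delta_cost / delta_effect
  list(ratio = ratio, quadrant = quadrant,
       delta_cost = delta_cost, delta_effect = delta_effect)
}

#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost`: the monetary value of the health gained at
#' willingness-to-pay `wtp` minus what it cost. Vectorised over all
#' arguments.
#'
#' @param effect Effect in effect units (QALYs, or SDQ-point improvement).
#' @param cost Cost in GBP.
#' @param wtp Willingness-to-pay (GBP per effect unit).
#' @return NMB in GBP.
#' @export
net_monetary_benefit <- function(effect, cost, wtp) {
  wtp * effect - cost
}

#' Willingness-to-pay grid
#'
#' @param values Nonnegative, strictly increasing GBP-per-effect-unit grid.
#' @param effect_label What one effect unit is (e.g. `"QALY"`,
#'   `"SDQ point improvement"`).
#' @return A `wtp_grid` object.
#' @export
wtp_grid <- function(values, effect_label = "QALY") {
  if (!length(values) || any(values < 0) || any(diff(values) <= 0) && length(values) > 1)
    abort_config("`values` must be nonnegative and strictly increasing",
                 "values")
  structure(list(values = as.numeric(values), effect_label = effect_label),
            class = "wtp_grid")
}

#' Default willingness-to-pay grids
#'
#' SDQ: GBP 0--1000 in steps of 1 per point improvement (no accepted
#' threshold exists for the SDQ, so a wide fine grid is scanned). QALY:
#' GBP 0--50 000 in steps of 500, spanning the NICE GBP 20 000--30 000
#' band.
#'
#' @param type `"sdq"` or `"qaly"`.
#' @return A [wtp_grid()].
#' @export
default_wtp_grid <- function(type = c("qaly", "sdq")) {
  type <- match.arg(type)
  if (type == "sdq") wtp_grid(seq(0, 1000, by = 1), "SDQ point improvement")
  else wtp_grid(seq(0, 50000, by = 500), "QALY")
}

#' Bootstrap the joint distribution of incremental costs and effects
#'
#' Non-parametric bootstrap of the *pair* of adjusted between-arm
#' differences: participants are resampled with replacement within arm
#' (stratified, preserving arm sizes), both adjusted models are refit on the
#' resample, and the (incremental cost, incremental effect) pair is stored.
#' Pairs come from the same resample, so their joint dependence is
#' preserved. Resamples whose fixed design is singular are redrawn (the
#' count is recorded); more than 10% redraws aborts, since the dataset is
#' then too degenerate for bootstrap inference.
#'
#' @param data A `trial_dataset` or participants data frame.
#' @param cost_spec,effect_spec [adjustment_spec()]s for the cost and effect
#'   outcomes.
#' @param B Number of bootstrap replicates (use >= 100, ideally thousands,
#'   for inference).
#' @param seed Integer seed; replicates are deterministic given it.
#' @param effect_direction `"higher_better"` (QALYs) keeps the arm
#'   coefficient as the effect; `"lower_better"` (SDQ) negates it so the
#'   effect reads as improvement.
#' @param .resampler Internal hook: function of the participants table
#'   returning row indices for one replicate. The default stratified-by-arm
#'   sampler is almost always what you want; an identity resampler turns
#'   the bootstrap into a point-estimate check.
#' @return An `incremental_distribution`: tibble `replicates` with columns
#'   `delta_cost`, `delta_effect`, plus `B`, `seed`, `effect_label`,
#'   `n_redrawn` and the point estimates.
#' @export
bootstrap_incrementals <- function(data, cost_spec, effect_spec, B = 5000,
                                   seed = 1L,
                                   effect_direction = c("higher_better",
                                                        "lower_better"),
                                   .resampler = NULL) {
  effect_direction <- match.arg(effect_direction)
  stopifnot(inherits(cost_spec, "adjustment_spec"),
            inherits(effect_spec, "adjustment_spec"))
  if (B < 1) abort_config("`B` must be >= 1", "B")
  df <- participants_of(data)
  sgn <- if (effect_direction == "lower_better") -1 else 1

  point_cost <- fit_arm_effect(df, cost_spec, quiet = TRUE)$estimate
  point_effect <- sgn * fit_arm_effect(df, effect_spec, quiet = TRUE)$estimate

  arm <- as.factor(df$arm)
  idx_by_arm <- split(seq_len(nrow(df)), arm)
  resampler <- .resampler %||% function(d) {
    unlist(lapply(idx_by_arm, function(ix) ix[sample.int(length(ix),
                                                         replace = TRUE)]),
           use.names = FALSE)
  }

  set.seed(seed)
  dc <- de <- numeric(B)
  redrawn <- 0L
  max_redraws <- max(10, ceiling(0.1 * B))
  b <- 1L
  while (b <= B) {
    rows <- df[resampler(df), ]
    fits <- tryCatch(
      list(cost = fit_arm_effect(rows, cost_spec, quiet = TRUE),
           eff = fit_arm_effect(rows, effect_spec, quiet = TRUE)),
      error = function(e) e)
    if (inherits(fits, "error")) {
      redrawn <- redrawn + 1L
      if (redrawn > max_redraws)
        stop("more than 10% of bootstrap resamples were degenerate; ",
             "the dataset does not support bootstrap inference",
             call. = FALSE)
      next
    }
    dc[b] <- fits$cost$estimate
    de[b] <- sgn * fits$eff$estimate
    b <- b + 1L
  }

  structure(list(
    replicates = tibble::tibble(delta_cost = dc, delta_effect = de),
    B = B, seed = seed, n_redrawn = redrawn,
    effect_label = effect_spec$outcome,
    point = c(delta_cost = point_cost, delta_effect = point_effect)),
    class = "incremental_distribution")
}

#' @export
print.incremental_distribution <- function(x, ...) {
  cat(sprintf("<incremental_distribution> B = %d (%d redrawn), effect: %s\n",
              x$B, x$n_redrawn, x$effect_label))
  cat(sprintf("  point: dCost %.2f, dEffect %.4g; replicate means %.2f / %.4g\n",
              x$point[["delta_cost"]], x$point[["delta_effect"]],
              mean(x$replicates$delta_cost), mean(x$replicates$delta_effect)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective: the fraction of bootstrap replicates with positive
#' incremental net monetary benefit `wtp * dEffect - dCost`, ties at exactly
#' zero counted as one half. The crossing threshold is the smallest grid
#' value at which the probability reaches 0.5.
#'
#' @param dist An `incremental_distribution`.
#' @param grid A [wtp_grid()].
#' @return A `ceac_curve`: tibble `curve` (`wtp`, `probability`),
#'   `crossing_lambda` (GBP, or `NA` if 0.5 is never reached), and labels.
#' @export
ceac <- function(dist, grid) {
  stopifnot(inherits(dist, "incremental_distribution"))
  if (!inherits(grid, "wtp_grid")) grid <- wtp_grid(grid)
  r <- dist$replicates
  if (!nrow(r)) abort_config("empty incremental distribution", "dist")
  prob <- vapply(grid$values, function(l) {
    nmb <- net_monetary_benefit(r$delta_effect, r$delta_cost, l)
    mean(nmb > 0) + 0.5 * mean(nmb == 0)
  }, numeric(1))
  cross <- grid$values[prob >= 0.5]
  structure(list(
    curve = tibble::tibble(wtp = grid$values, probability = prob),
    crossing_lambda = if (length(cross)) cross[1] else NA_real_,
    effect_label = grid$effect_label, B = dist$B),
    class = "ceac_curve")
}

#' @export
print.ceac_curve <- function(x, ...) {
  cat(sprintf("<ceac_curve> %d grid points (%s), B = %d\n",
              nrow(x$curve), x$effect_label, x$B))
  cat(sprintf("  P(cost-effective) range %.3f to %.3f; crosses 0.5 at %s\n",
              min(x$curve$probability), max(x$curve$probability),
              if (is.na(x$crossing_lambda)) "no grid value"
              else sprintf("GBP %g", x$crossing_lambda)))
  invisible(x)
}

scenario_registry <- function() {
  tibble::tribble(
    ~outcome_token,    ~outcome_col,     ~direction,      ~grid_type,
    "sdq_12m",         "sdq_12",         "lower_better",  "sdq",
    "sdq_6m",          "sdq_6",          "lower_better",  "sdq",
    "qaly_cyp",        "qaly_cyp",       "higher_better", "qaly",
    "qaly_caregiver",  "qaly_caregiver", "higher_better", "qaly",
    "qaly_combined",   "qaly_combined",  "higher_better", "qaly"
  )
}

#' Run a set of cost-effectiveness scenarios
#'
#' Each scenario is an outcome (`sdq_12m`, `sdq_6m`, `qaly_cyp`,
#' `qaly_caregiver`, `qaly_combined`) crossed with a data handling
#' (`complete_case` or `imputed`) and an intervention costing (`full` or
#' `s75`, the 75% substitution scenario). For every scenario the adjusted
#' incremental cost and effect, the ICER, a bootstrap CEAC and its 0.5
#' crossing are computed. The same seed is used for every scenario so the
#' curves are comparable replicate-by-replicate.
#'
#' @param dataset A costed, QALY-augmented `trial_dataset`.
#' @param scenarios Data frame with columns `outcome`, `data`, `costing`
#'   (see [scenario_grid()]), or a character vector of outcome tokens which
#'   is expanded with complete-case handling and full costing.
#' @param B Bootstrap replicates per scenario.
#' @param seed Master seed shared across scenarios.
#' @param imputation An [imputation_config()], required when any scenario
#'   uses imputed data.
#' @param estimator Estimator for the adjusted models.
#' @param wtp_probability_band GBP band over which the reported probability
#'   range is read for QALY scenarios (NICE's indicative band by default).
#' @return A tibble with one row per scenario: adjusted `delta_cost` and
#'   `delta_effect`, `icer`, `quadrant`, `crossing_lambda`, probability at
#'   the band ends, and the `ceac_curve` object in a list column.
#' @export
run_scenarios <- function(dataset, scenarios = scenario_grid(), B = 1000,
                          seed = 1L, imputation = NULL,
                          estimator = "mixed_random_intercept",
                          wtp_probability_band = c(20000, 30000)) {
  if (is.character(scenarios))
    scenarios <- scenario_grid(outcome = scenarios, data = "complete_case",
                               costing = "full")
  reg <- scenario_registry()
  bad <- setdiff(scenarios$outcome, reg$outcome_token)
  if (length(bad))
    abort_config(paste("unknown scenario outcome token(s):",
                       paste(bad, collapse = ", ")), "scenarios")
  bad <- setdiff(scenarios$data, c("complete_case", "imputed"))
  if (length(bad))
    abort_config(paste("unknown data handling:", paste(bad, collapse = ", ")),
                 "scenarios")
  bad <- setdiff(scenarios$costing, c("full", "s75"))
  if (length(bad))
    abort_config(paste("unknown costing token(s):",
                       paste(bad, collapse = ", ")), "scenarios")
  if (any(scenarios$data == "imputed") && is.null(imputation))
    abort_config("imputed scenarios need an `imputation` config",
                 "imputation")

  imputed_sets <- NULL
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    info <- reg[reg$outcome_token == sc$outcome, ]
    ds <- if (sc$costing == "s75") scale_intervention(dataset, 0.75) else dataset
    cost_spec <- default_adjustment_spec("cost_total", estimator = estimator)
    eff_spec <- default_adjustment_spec(info$outcome_col,
                                        estimator = estimator)
    grid <- default_wtp_grid(info$grid_type)
    band <- if (info$grid_type == "qaly") wtp_probability_band
            else range(grid$values)

    if (sc$data == "imputed") {
      if (is.null(imputed_sets))
        imputed_sets <<- impute_chained(dataset, imputation)
      sets <- imputed_sets
      if (sc$costing == "s75")
        sets <- lapply(sets, scale_intervention, factor = 0.75)
      cc <- ceac_under_mi(sets, cost_spec, eff_spec, grid, B = B,
                          seed = seed,
                          effect_direction = info$direction)
      dist <- attr(cc, "distribution")
    } else {
      dist <- bootstrap_incrementals(ds, cost_spec, eff_spec, B = B,
                                     seed = seed,
                                     effect_direction = info$direction)
      cc <- ceac(dist, grid)
    }
    ic <- icer(dist$point[["delta_cost"]], dist$point[["delta_effect"]])
    p_band <- vapply(band, function(l) {
      cc$curve$probability[which.min(abs(cc$curve$wtp - l))]
    }, numeric(1))
    tibble::tibble(
      outcome = sc$outcome, data = sc$data, costing = sc$costing,
      delta_cost = dist$point[["delta_cost"]],
      delta_effect = dist$point[["delta_effect"]],
      icer = ic$ratio, quadrant = ic$quadrant,
      crossing_lambda = cc$crossing_lambda,
      prob_at_band_low = p_band[1], prob_at_band_high = p_band[length(p_band)],
      ceac = list(cc))
  })
  dplyr::bind_rows(rows)
}

#' Scenario grid helper
#'
#' @param outcome,data,costing Vectors of scenario tokens; the full cross
#'   product is returned.
#' @return Tibble with columns `outcome`, `data`, `costing`.
#' @export
scenario_grid <- function(outcome = c("sdq_12m", "sdq_6m", "qaly_cyp",
                                      "qaly_caregiver", "qaly_combined"),
                          data = "complete_case",
                          costing = "full") {
  tidyr::expand_grid(outcome = outcome, data = data, costing = costing)
}
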