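#' Run the full economic evaluation and write result tables
#'
#' Produces, from a costed and QALY-augmented dataset, the standard
#' within-trial evaluation outputs: per-category and total costs by arm
#' (`table1_costs.csv`), unadjusted and adjusted outcome comparisons
#' (`table2_outcomes.csv`), scenario ICERs with CEAC crossings and
#' probability bands (`table3_icers.csv`), one CEAC CSV per scenario
#' (`ceac_<outcome>_<data>_<costing>.csv` with columns
#' `wtp, probability, scenario`), and `run_log.yaml` recording the seed,
#' scenario set, bootstrap size and a hash of the generating configuration.
#' Monetary values are rounded to pence at write time only.
#'
#' @param dataset A `trial_dataset` (run [cost_trial()] and [add_qalys()]
#'   first, and optionally [apply_missingness()]).
#' @param out_dir Output directory (created if absent).
#' @param scenarios Scenario table as in [run_scenarios()].
#' @param B Bootstrap replicates per scenario.
#' @param seed Master seed shared by all scenarios.
#' @param imputation Optional [imputation_config()] for imputed scenarios.
#' @param estimator Estimator for adjusted models.
#' @return Invisibly, the scenario results tibble from [run_scenarios()].
#' @export
run_analysis <- function(dataset, out_dir, scenarios = scenario_grid(),
                         B = 1000, seed = 1L, imputation = NULL,
                         estimator = "mixed_random_intercept") {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  write.csv(costs_by_arm_table(dataset),
            file.path(out_dir, "table1_costs.csv"), row.names = FALSE)
  write.csv(outcomes_table(dataset, estimator = estimator),
            file.path(out_dir, "table2_outcomes.csv"), row.names = FALSE)

  res <- run_scenarios(dataset, scenarios, B = B, seed = seed,
                       imputation = imputation, estimator = estimator)
  t3 <- res[setdiff(names(res), "ceac")]
  for (col in c("delta_cost", "icer", "crossing_lambda"))
    t3[[col]] <- round_gbp(t3[[col]])
  write.csv(t3, file.path(out_dir, "table3_icers.csv"), row.names = FALSE)

  for (i in seq_len(nrow(res))) {
    tag <- paste(res$outcome[i], res$data[i], res$costing[i], sep = "_")
    cc <- res$ceac[[i]]$curve
    cc$scenario <- tag
    write.csv(cc, file.path(out_dir, paste0("ceac_", tag, ".csv")),
              row.names = FALSE)
  }

  yaml::write_yaml(list(
    seed = seed, B = B,
    scenarios = apply(scenarios, 1, paste, collapse = "|"),
    estimator = estimator,
    m_imputations = if (is.null(imputation)) NULL else
      imputation$m_imputations,
    config_hash = rlang::hash(dataset$config),
    package_version = as.character(utils::packageVersion("trialcea")),
    r_version = R.version.string
  ), file.path(out_dir, "run_log.yaml"))

  invisible(res)
}

#' Costs by arm, mirroring a trial cost table
#'
#' Per-category 12-month follow-up costs (mean, SD, and percentage of
#' participants with any use) by arm, with totals excluding and including
#' the intervention and the unadjusted mean difference with its Welch
#' t-test p-value.
#'
#' @param dataset A costed `trial_dataset`.
#' @param table The [unit_cost_table()] used to price records.
#' @return A tibble, one row per category plus total rows.
#' @export
costs_by_arm_table <- function(dataset, table = default_unit_costs()) {
  p <- dataset$participants
  fu <- dataset$service_use[dataset$service_use$period %in%
                              c("m0_6", "m6_12"), ]
  bd <- cost_service_use(fu, table, participants = p$participant_id,
                         periods = c("m0_6", "m6_12"))
  percat <- bd |>
    dplyr::group_by(.data$participant_id, .data$category) |>
    dplyr::summarise(cost = sum(.data$cost), any_use = any(.data$quantity > 0),
                     .groups = "drop") |>
    dplyr::left_join(p[c("participant_id", "arm")], by = "participant_id")
  cat_rows <- percat |>
    dplyr::group_by(.data$category, .data$arm) |>
    dplyr::summarise(mean = mean(.data$cost), sd = sd(.data$cost),
                     pct_any = 100 * mean(.data$any_use), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = c("mean", "sd", "pct_any"))

  total_row <- function(col, label) {
    um <- unadjusted_means(p, col)
    tibble::tibble(category = label,
                   mean_control = um$by_arm$mean[1],
                   mean_intervention = um$by_arm$mean[2],
                   sd_control = um$by_arm$sd[1],
                   sd_intervention = um$by_arm$sd[2],
                   difference = um$difference, p_value = um$p_value)
  }
  out <- dplyr::bind_rows(
    cat_rows,
    total_row("cost_excl_intervention", "total_excl_intervention"),
    total_row("cost_intervention", "intervention"),
    total_row("cost_total", "total_incl_intervention"))
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "p_value"
  out[num] <- lapply(out[num], round_gbp)
  out
}

#' Outcome comparisons, unadjusted and adjusted
#'
#' For each outcome (SDQ at 6 and 12 months, QALYs for children, caregivers
#' and combined, and total costs excluding/including the intervention):
#' per-arm complete-case means and SDs, and the covariate-adjusted
#' between-arm difference with Wald 95% interval.
#'
#' @param dataset A costed, QALY-augmented `trial_dataset`.
#' @param estimator Estimator for [adjusted_difference()].
#' @return A tibble, one row per outcome.
#' @export
outcomes_table <- function(dataset, estimator = "mixed_random_intercept") {
  outs <- c("sdq_6", "sdq_12", "qaly_cyp", "qaly_caregiver", "qaly_combined",
            "cost_excl_intervention", "cost_total")
  rows <- lapply(intersect(outs, names(dataset$participants)), function(o) {
    um <- unadjusted_means(dataset, o)
    ad <- adjusted_difference(dataset, default_adjustment_spec(o,
                                                               estimator = estimator))
    tibble::tibble(outcome = o,
                   n_control = um$by_arm$n[1],
                   n_intervention = um$by_arm$n[2],
                   mean_control = um$by_arm$mean[1],
                   mean_intervention = um$by_arm$mean[2],
                   sd_control = um$by_arm$sd[1],
                   sd_intervention = um$by_arm$sd[2],
                   unadjusted_difference = um$difference,
                   adjusted_difference = ad$estimate,
                   ci_low = ad$ci_low, ci_high = ad$ci_high,
                   p_value = ad$p_value, n_used = ad$n_used,
                   model = ad$model_tag)
  })
  dplyr::bind_rows(rows)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A `ceac_curve`, or the tibble from [run_scenarios()] (one line
#'   per scenario).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ceac <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ceac() needs the ggplot2 package", call. = FALSE)
  df <- if (inherits(x, "ceac_curve")) {
    dplyr::mutate(x$curve, scenario = x$effect_label)
  } else {
    dplyr::bind_rows(lapply(seq_len(nrow(x)), function(i) {
      dplyr::mutate(x$ceac[[i]]$curve,
                    scenario = paste(x$outcome[i], x$data[i], x$costing[i],
                                     sep = " / "))
    }))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per effect unit)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}
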