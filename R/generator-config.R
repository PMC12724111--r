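#' Configuration for the synthetic trial generator
#'
#' Builds and validates the parameter set that [generate_trial()] uses to
#' simulate a two-arm, multi-site randomised trial with skewed service-use
#' costs, bounded utility trajectories (children and caregivers), an integer
#' symptom score (SDQ total difficulties, 0--40) and per-participant
#' intervention session counts. Defaults describe a 334-participant, 13-site
#' trial of a modular psychological intervention: treatment effects are
#' *conditional* effects (they hold given baseline covariates), so the
#' covariate-adjusted estimators in [adjusted_difference()] are calibrated to
#' recover them.
#'
#' Cost structure: baseline 3-month costs are gamma with arm-specific means
#' (a deliberate baseline imbalance so adjustment machinery is exercised);
#' follow-up costs (two 6-month periods) are gamma with a conditional mean
#' linear in baseline cost plus the arm effect. Utilities are generated on a
#' latent normal scale (participant random intercept + occasion noise) and
#' clipped to `[0, 1]`; defaults keep clipping below ~2% so the configured
#' QALY effects survive clipping essentially unattenuated. The treatment
#' effect on utilities is placed equally on the 6- and 12-month occasions and
#' scaled by 1/0.75 so the trapezoidal QALY contrast equals the configured
#' QALY effect.
#'
#' @param n_participants Total sample size.
#' @param allocation Named integer vector `c(intervention=, control=)`;
#'   must sum to `n_participants`.
#' @param n_sites Number of recruiting sites (random-intercept clusters).
#' @param effect_sdq_6m,effect_sdq_12m Conditional treatment effect
#'   (intervention minus control) on the SDQ at 6 and 12 months; negative
#'   means benefit.
#' @param effect_qaly_cyp Conditional effect on child QALYs over 1 year.
#' @param effect_qaly_caregiver Conditional effect on caregiver QALYs.
#' @param effect_cost_excl_intervention Conditional effect (GBP) on 12-month
#'   cost excluding the intervention.
#' @param baseline_cost_mean Named pair of baseline 3-month cost means (GBP)
#'   by arm; unequal values create baseline imbalance.
#' @param followup_cost_mean_control Control-arm mean 12-month cost excluding
#'   the intervention (GBP).
#' @param baseline_cost_coef Slope linking baseline cost to expected
#'   follow-up cost (per GBP).
#' @param cost_shape Gamma shape for cost draws; smaller = more right-skew.
#' @param sdq_mean_baseline Control-arm baseline SDQ mean.
#' @param sdq_trend_control Control-arm SDQ means at 6 and 12 months.
#' @param sdq_between_sd,sdq_within_sd SDQ participant-level and occasion
#'   noise SDs (points).
#' @param utility_means List with elements `cyp` and `caregiver`, each a
#'   length-3 vector of control-arm utility means at 0, 6, 12 months.
#' @param utility_between_sd,utility_within_sd Latent utility SDs.
#' @param utility_range Admissible utility interval; default `c(0, 1)`.
#'   Widen to `c(-0.594, 1)` to admit worse-than-dead EQ-5D-5L states.
#' @param site_sd Named list of site random-intercept SDs for `cost` (GBP,
#'   applied to 12-month follow-up cost), `sdq` (points), `utility`.
#' @param session_range Integer `c(min, max)` intervention sessions attended.
#' @param session_mean Target mean sessions in the intervention arm; the
#'   discrete session distribution is calibrated so its mean matches exactly.
#' @param cost_per_session Cost (GBP) per delivered session used when pricing
#'   the generated intervention exposure.
#' @param missingness Named list of per-measure follow-up missingness
#'   proportions, each `c(m6=, m12=)`, for `sdq`, `cost`, `utility_cyp`,
#'   `utility_caregiver`. Missingness is monotone within measure (missing at
#'   6 months implies missing at 12).
#' @param missingness_mechanism `"MAR"` (logistic in baseline SDQ and
#'   log baseline cost) or `"MCAR"`.
#' @param mar_coef Log-odds coefficients for the MAR link, per SD of
#'   baseline SDQ (`sdq`) and of log1p baseline cost (`log_cost`).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#'
#' @return An object of class `trial_config` (a validated list).
#' @seealso [generate_trial()], [apply_missingness()]
#' @export
trial_config <- function(n_participants = 334,
                         allocation = c(intervention = 167, control = 167),
                         n_sites = 13,
                         effect_sdq_6m = -2.0,
                         effect_sdq_12m = -2.021,
                         effect_qaly_cyp = 0.023,
                         effect_qaly_caregiver = 0.070,
                         effect_cost_excl_intervention = -796,
                         baseline_cost_mean = c(intervention = 1602, control = 2076),
                         followup_cost_mean_control = 7845,
                         baseline_cost_coef = 0.8,
                         cost_shape = 1.2,
                         sdq_mean_baseline = 19.5,
                         sdq_trend_control = c(19, 18.5),
                         sdq_between_sd = 4,
                         sdq_within_sd = 4,
                         utility_means = list(cyp = c(0.70, 0.70, 0.70),
                                              caregiver = c(0.70, 0.70, 0.70)),
                         utility_between_sd = 0.07,
                         utility_within_sd = 0.07,
                         utility_range = c(0, 1),
                         site_sd = list(cost = 300, sdq = 1, utility = 0.02),
                         session_range = c(2L, 23L),
                         session_mean = 18.23,
                         cost_per_session = 80.41,
                         missingness = list(
                           sdq = c(m6 = 0.16, m12 = 0.22),
                           cost = c(m6 = 0.16, m12 = 0.22),
                           utility_cyp = c(m6 = 0.20, m12 = 0.35),
                           utility_caregiver = c(m6 = 0.20, m12 = 0.35)
                         ),
                         missingness_mechanism = c("MAR", "MCAR"),
                         mar_coef = c(sdq = 0.5, log_cost = 0.3),
                         seed = 1L) {
  missingness_mechanism <- match.arg(missingness_mechanism)
  cfg <- list(
    n_participants = as.integer(n_participants),
    allocation = allocation, n_sites = as.integer(n_sites),
    effect_sdq_6m = effect_sdq_6m, effect_sdq_12m = effect_sdq_12m,
    effect_qaly_cyp = effect_qaly_cyp,
    effect_qaly_caregiver = effect_qaly_caregiver,
    effect_cost_excl_intervention = effect_cost_excl_intervention,
    baseline_cost_mean = baseline_cost_mean,
    followup_cost_mean_control = followup_cost_mean_control,
    baseline_cost_coef = baseline_cost_coef,
    cost_shape = cost_shape,
    sdq_mean_baseline = sdq_mean_baseline,
    sdq_trend_control = sdq_trend_control,
    sdq_between_sd = sdq_between_sd, sdq_within_sd = sdq_within_sd,
    utility_means = utility_means,
    utility_between_sd = utility_between_sd,
    utility_within_sd = utility_within_sd,
    utility_range = utility_range,
    site_sd = site_sd,
    session_range = as.integer(session_range),
    session_mean = session_mean,
    cost_per_session = cost_per_session,
    missingness = missingness,
    missingness_mechanism = missingness_mechanism,
    mar_coef = mar_coef,
    seed = as.integer(seed)
  )
  validate_trial_config(cfg)
}

validate_trial_config <- function(cfg) {
  if (cfg$n_participants < 2L)
    abort_config("`n_participants` must be at least 2", "n_participants")
  if (!setequal(names(cfg$allocation), c("intervention", "control")))
    abort_config("`allocation` must be named c(intervention=, control=)", "allocation")
  if (sum(cfg$allocation) != cfg$n_participants)
    abort_config(sprintf(
      "`allocation` counts (%d) must sum to `n_participants` (%d)",
      sum(cfg$allocation), cfg$n_participants), "allocation")
  if (cfg$n_sites < 1L) abort_config("`n_sites` must be >= 1", "n_sites")
  if (cfg$cost_shape <= 0) abort_config("`cost_shape` must be > 0", "cost_shape")
  if (any(cfg$baseline_cost_mean <= 0))
    abort_config("`baseline_cost_mean` entries must be > 0", "baseline_cost_mean")
  for (role in c("cyp", "caregiver")) {
    u <- cfg$utility_means[[role]]
    if (length(u) != 3L || any(u < cfg$utility_range[1]) || any(u > cfg$utility_range[2]))
      abort_config(sprintf(
        "`utility_means$%s` must be 3 values inside [%g, %g]",
        role, cfg$utility_range[1], cfg$utility_range[2]), "utility_means")
  }
  sr <- cfg$session_range
  if (length(sr) != 2L || sr[1] > sr[2] || sr[1] < 0)
    abort_config("`session_range` must be nonnegative c(min, max)", "session_range")
  if (cfg$session_mean < sr[1] || cfg$session_mean > sr[2])
    abort_config("`session_mean` must lie within `session_range`", "session_mean")
  for (ms in names(cfg$missingness)) {
    r <- cfg$missingness[[ms]]
    if (any(r < 0) || any(r > 1))
      abort_config(sprintf("`missingness$%s` proportions must be in [0, 1]", ms),
                   "missingness")
  }
  if (cfg$sdq_mean_baseline < 0 || cfg$sdq_mean_baseline > 40)
    abort_config("`sdq_mean_baseline` must be in [0, 40]", "sdq_mean_baseline")
  structure(cfg, class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf("  n = %d (%d intervention / %d control), %d sites, seed %d\n",
              x$n_participants, x$allocation[["intervention"]],
              x$allocation[["control"]], x$n_sites, x$seed))
  cat(sprintf("  effects: SDQ(12m) %+.3f, QALY cyp %+.3f / caregiver %+.3f, cost excl %+.0f GBP\n",
              x$effect_sdq_12m, x$effect_qaly_cyp, x$effect_qaly_caregiver,
              x$effect_cost_excl_intervention))
  cat(sprintf("  sessions %d-%d (mean %.2f) at %.2f GBP; missingness %s\n",
              x$session_range[1], x$session_range[2], x$session_mean,
              x$cost_per_session, x$missingness_mechanism))
  invisible(x)
}

# Discrete session-count distribution on session_range with geometric decay
# away from the maximum (most participants complete most sessions, a long
# left tail of early dropout). The decay rate is solved so the exact discrete
# mean equals `session_mean`.
session_count_probs <- function(range, mean) {
  s <- seq.int(range[1], range[2])
  if (range[1] == range[2]) return(setNames(1, s))
  mean_at <- function(log_tau) {
    w <- exp(-(range[2] - s) / exp(log_tau))
    sum(s * w) / sum(w)
  }
  # tau -> 0 gives mean -> max; tau -> Inf gives the uniform mean
  lo <- -6; hi <- 12
  if (mean >= range[2]) return(setNames(as.numeric(s == range[2]), s))
  if (mean <= mean_at(hi)) {
    # target below the uniform mean: decay away from the minimum instead
    mean_at <- function(log_tau) {
      w <- exp(-(s - range[1]) / exp(log_tau))
      sum(s * w) / sum(w)
    }
    root <- uniroot(function(lt) mean_at(lt) - mean, c(lo, hi), tol = 1e-12)
    w <- exp(-(s - range[1]) / exp(root$root))
  } else {
    root <- uniroot(function(lt) mean_at(lt) - mean, c(lo, hi), tol = 1e-12)
    w <- exp(-(range[2] - s) / exp(root$root))
  }
  setNames(w / sum(w), s)
}
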