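#' Specify a covariate-adjusted between-arm comparison
#'
#' Captures the model for one outcome: the outcome column, its baseline
#' covariates (baseline cost, baseline SDQ and — for QALY outcomes — the
#' relevant baseline utility), the four categorical minimisation factors,
#' the clustering column for the random intercept, and the estimator.
#'
#' @param outcome Outcome column name on the participants table.
#' @param baseline_covariates Character vector of baseline adjustment
#'   columns; must not contain the outcome.
#' @param minimisation_factors Categorical balancing factors entering as
#'   fixed effects.
#' @param cluster Column with the recruiting-site identifier.
#' @param estimator `"mixed_random_intercept"` (site random intercept via
#'   lme4) or `"ols_fallback"` (plain least squares).
#' @return An `adjustment_spec` object.
#' @export
adjustment_spec <- function(outcome,
                            baseline_covariates = c("cost_baseline", "sdq_0"),
                            minimisation_factors = c("disorder", "age_group",
                                                     "asd",
                                                     "intellectual_disability"),
                            cluster = "site_id",
                            estimator = c("mixed_random_intercept",
                                          "ols_fallback")) {
  estimator <- match.arg(estimator)
  if (outcome %in% baseline_covariates)
    abort_config("the outcome cannot also be an adjustment covariate",
                 "baseline_covariates")
  structure(list(outcome = outcome, baseline_covariates = baseline_covariates,
                 minimisation_factors = minimisation_factors,
                 cluster = cluster, estimator = estimator),
            class = "adjustment_spec")
}

#' Default adjustment specifications per outcome
#'
#' Every analysis adjusts for baseline cost, baseline SDQ and the
#' minimisation factors; QALY outcomes additionally adjust for the
#' corresponding baseline utility score(s).
#'
#' @param outcome One of `"sdq_6"`, `"sdq_12"`, `"qaly_cyp"`,
#'   `"qaly_caregiver"`, `"qaly_combined"`, `"cost_total"`,
#'   `"cost_excl_intervention"`.
#' @param estimator Passed through to [adjustment_spec()].
#' @return An `adjustment_spec`.
#' @export
default_adjustment_spec <- function(outcome,
                                    estimator = "mixed_random_intercept") {
  extra <- switch(outcome,
    qaly_cyp = "utility_cyp_0",
    qaly_caregiver = "utility_caregiver_0",
    qaly_combined = c("utility_cyp_0", "utility_caregiver_0"),
    character(0))
  adjustment_spec(outcome,
                  baseline_covariates = c("cost_baseline", "sdq_0", extra),
                  estimator = estimator)
}

participants_of <- function(data) {
  if (inherits(data, "trial_dataset")) data$participants else
    tibble::as_tibble(data)
}

spec_columns <- function(spec) {
  c(spec$outcome, "arm", spec$baseline_covariates,
    spec$minimisation_factors, spec$cluster)
}

fixed_formula <- function(spec) {
  rhs <- c("arm", spec$baseline_covariates, spec$minimisation_factors)
  as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + ")))
}

# Core fitter shared by adjusted_difference() and the bootstrap: returns the
# arm coefficient, its SE and bookkeeping, or signals a classed
# "trialcea_singular_fit" error on a rank-deficient fixed design.
fit_arm_effect <- function(df, spec, quiet = FALSE) {
  df <- df[complete.cases(df[spec_columns(spec)]), spec_columns(spec)]
  df$arm <- droplevels(as.factor(df$arm))
  # centre/scale continuous covariates: leaves the arm coefficient
  # untouched and keeps the mixed-model optimiser well conditioned
  for (cv in spec$baseline_covariates) {
    if (is.numeric(df[[cv]]) && length(unique(df[[cv]])) > 1L && sd(df[[cv]]) > 0)
      df[[cv]] <- (df[[cv]] - mean(df[[cv]])) / sd(df[[cv]])
  }
  if (nlevels(df$arm) != 2L || min(table(df$arm)) < 2L)
    stop("need at least 2 complete observations in each arm", call. = FALSE)
  arm_level <- levels(df$arm)[2]

  X <- model.matrix(fixed_formula(spec), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(structure(class = c("trialcea_singular_fit", "error", "condition"),
                   list(message = paste("singular design; collinear columns:",
                                        paste(dropped, collapse = ", ")),
                        call = NULL)))
  }

  cl <- droplevels(as.factor(df[[spec$cluster]]))
  use_mixed <- spec$estimator == "mixed_random_intercept" && nlevels(cl) > 1L
  if (spec$estimator == "mixed_random_intercept" && !use_mixed && !quiet)
    warning("single cluster level: falling back to OLS", call. = FALSE)

  if (use_mixed) {
    fml <- as.formula(paste(paste(deparse(fixed_formula(spec)),
                                  collapse = " "),
                            "+ (1 |", spec$cluster, ")"))
    fit <- suppressMessages(lme4::lmer(
      fml, data = df,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    co <- paste0("arm", arm_level)
    est <- lme4::fixef(fit)[[co]]
    se <- sqrt(as.matrix(vcov(fit))[co, co])
    tag <- "mixed_random_intercept"
  } else {
    fit <- lm(fixed_formula(spec), data = df)
    co <- paste0("arm", arm_level)
    est <- coef(fit)[[co]]
    # suppressWarnings: summary.lm complains about zero-residual fits that
    # arise legitimately in tiny bootstrap resamples
    se <- sqrt(suppressWarnings(vcov(fit)[co, co]))
    tag <- "ols"
  }
  list(estimate = est, se = se, n_used = nrow(df), model_tag = tag,
       arm_level = arm_level)
}

#' Covariate-adjusted between-arm difference
#'
#' Fits a linear model of the outcome on arm, baseline covariates and
#' minimisation factors with a recruiting-site random intercept (lme4),
#' restricted to rows complete for this analysis's columns, and returns the
#' arm coefficient (second arm level minus reference, i.e. intervention
#' minus control under the default coding) with Wald 95% limits. Falls back
#' to OLS, with a warning, when only one cluster level is present; a
#' rank-deficient fixed design is an error naming the collinear columns.
#'
#' @param data A `trial_dataset` or participants data frame.
#' @param spec An [adjustment_spec()].
#' @param conf_level Confidence level for the Wald interval.
#' @param quiet Suppress the OLS-fallback warning (used inside resampling
#'   loops).
#' @return A `difference_estimate`: list with `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `n_used`, `model_tag`, `outcome`.
#' @export
adjusted_difference <- function(data, spec, conf_level = 0.95,
                                quiet = FALSE) {
  stopifnot(inherits(spec, "adjustment_spec"))
  df <- participants_of(data)
  missing_cols <- setdiff(spec_columns(spec), names(df))
  if (length(missing_cols))
    abort_config(paste("columns absent from data:",
                       paste(missing_cols, collapse = ", ")), "spec")
  f <- fit_arm_effect(df, spec, quiet = quiet)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(estimate = f$estimate, se = f$se,
                 ci_low = f$estimate - zq * f$se,
                 ci_high = f$estimate + zq * f$se,
                 p_value = 2 * pnorm(-abs(f$estimate / f$se)),
                 n_used = f$n_used, model_tag = f$model_tag,
                 outcome = spec$outcome),
            class = "difference_estimate")
}

#' @export
print.difference_estimate <- function(x, ...) {
  cat(sprintf("<difference_estimate> %s [%s, n=%d]\n", x$outcome,
              x$model_tag, x$n_used))
  cat(sprintf("  %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
              x$estimate, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Unadjusted per-arm means and their difference
#'
#' Arithmetic means by arm with a Welch two-sample t-test on the difference
#' (intervention minus control). Parametric comparison of means is the
#' standard choice for cost data, skewness notwithstanding, because the
#' arithmetic mean is the decision-relevant statistic.
#'
#' @param data A `trial_dataset` or participants data frame.
#' @param outcome Outcome column name.
#' @return A list with `by_arm` (tibble: arm, n, mean, sd), `difference`,
#'   `t_statistic`, `p_value`.
#' @export
unadjusted_means <- function(data, outcome) {
  df <- participants_of(data)
  y <- df[[outcome]]
  keep <- !is.na(y)
  y <- y[keep]; arm <- droplevels(as.factor(df$arm[keep]))
  if (nlevels(arm) != 2L || min(table(arm)) < 1L)
    stop("need observations in both arms", call. = FALSE)
  arm_levels <- levels(arm)
  arm_n <- as.integer(table(arm))
  arm_mean <- unname(vapply(arm_levels, function(a) mean(y[arm == a]),
                            numeric(1)))
  arm_sd <- unname(vapply(arm_levels, function(a) sd(y[arm == a]),
                          numeric(1)))
  by_arm <- tibble::tibble(arm = arm_levels, n = arm_n, mean = arm_mean,
                           sd = arm_sd)
  diff <- arm_mean[2] - arm_mean[1]
  tt <- tryCatch(
    if (all(by_arm$n >= 2))
      t.test(y[arm == levels(arm)[2]], y[arm == levels(arm)[1]])
    else list(statistic = NA_real_, p.value = NA_real_),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  list(by_arm = by_arm, difference = diff,
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
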