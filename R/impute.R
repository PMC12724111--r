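#' Configuration for chained-equation multiple imputation
#'
#' Predictive-mean-matching imputation of the analysis outcomes (period
#' costs, QALYs and SDQ per follow-up timepoint). The univariate model for
#' each incomplete variable is a linear regression on the other outcomes,
#' arm, the four minimisation factors and the always-observed baseline
#' measures; matching is type 1 (observed cases scored with the posterior
#' mean, missing cases with a parameter draw), with a donor pool of
#' `donors_k` nearest predictions from which one donor's observed value is
#' sampled. Variables are visited in ascending order of missingness
#' fraction, for `iterations` sweeps of the chain.
#'
#' @param m_imputations Number of completed datasets (default 31).
#' @param donors_k Donor pool size (default 5).
#' @param iterations Chain sweeps per imputation (default 10).
#' @param variables Outcome columns eligible for imputation.
#' @param predictors Always-observed columns entering every univariate
#'   model in addition to the other outcomes.
#' @param seed Integer seed; the full run is deterministic given it.
#' @return An `imputation_config` object.
#' @export
imputation_config <- function(m_imputations = 31, donors_k = 5,
                              iterations = 10,
                              variables = c("cost_0_6", "cost_6_12",
                                            "sdq_6", "sdq_12",
                                            "qaly_cyp", "qaly_caregiver"),
                              predictors = c("arm", "disorder", "age_group",
                                             "asd", "intellectual_disability",
                                             "cost_baseline", "sdq_0",
                                             "utility_cyp_0",
                                             "utility_caregiver_0"),
                              seed = 1L) {
  if (m_imputations < 2) abort_config("`m_imputations` must be >= 2",
                                      "m_imputations")
  if (donors_k < 1) abort_config("`donors_k` must be >= 1", "donors_k")
  if (iterations < 1) abort_config("`iterations` must be >= 1", "iterations")
  structure(list(m_imputations = as.integer(m_imputations),
                 donors_k = as.integer(donors_k),
                 iterations = as.integer(iterations),
                 variables = variables, predictors = predictors,
                 seed = as.integer(seed)),
            class = "imputation_config")
}

# One univariate PMM draw for variable `v` given completed data `dat`.
pmm_draw <- function(dat, v, rhs_vars, mis, k) {
  obs <- which(!mis)
  y <- dat[[v]][obs]
  X <- model.matrix(as.formula(paste("~", paste(rhs_vars, collapse = " + "))),
                    dat)
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[mis, , drop = FALSE]
  XtX <- crossprod(Xo)
  ridge <- diag(ncol(XtX)) * 1e-8 * mean(diag(XtX))
  R <- chol(XtX + ridge)
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(Xo, y)))
  resid <- y - Xo %*% beta_hat
  df <- max(length(obs) - ncol(Xo), 1)
  sigma2_star <- sum(resid^2) / rchisq(1, df)
  V <- chol2inv(R)
  beta_star <- beta_hat + t(chol(V)) %*% rnorm(ncol(Xo)) * sqrt(sigma2_star)
  yhat_obs <- as.numeric(Xo %*% beta_hat)
  yhat_mis <- as.numeric(Xm %*% beta_star)
  vapply(yhat_mis, function(p) {
    donors <- order(abs(yhat_obs - p))[seq_len(k)]
    y[donors[sample.int(k, 1)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' @param dataset A `trial_dataset` whose participants table carries the
#'   outcome columns named in the config (run [cost_trial()] and
#'   [add_qalys()] first) with missingness only in those columns.
#' @param config An [imputation_config()].
#' @return A list of `m_imputations` completed `trial_dataset`s. Every
#'   imputed value equals some observed value of its variable (the PMM
#'   support property); derived totals (`cost_excl_intervention`,
#'   `cost_total`, `qaly_combined`) are recomputed from the imputed
#'   constituents. With no missing values the result is `m` identical
#'   copies of the input.
#' @export
impute_chained <- function(dataset, config = imputation_config()) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(config, "imputation_config"))
  p <- dataset$participants
  vars <- intersect(config$variables, names(p))
  missing_pred <- setdiff(config$predictors, names(p))
  if (length(missing_pred))
    abort_config(paste("predictors absent from data:",
                       paste(missing_pred, collapse = ", ")), "predictors")
  if (anyNA(p[config$predictors]))
    abort_config("imputation predictors must be fully observed", "predictors")

  mis_frac <- vapply(vars, function(v) mean(is.na(p[[v]])), numeric(1))
  to_impute <- vars[mis_frac > 0]
  short <- to_impute[vapply(to_impute,
                            function(v) sum(!is.na(p[[v]])) < config$donors_k,
                            logical(1))]
  if (length(short))
    abort_config(paste("fewer observed values than `donors_k` for:",
                       paste(short, collapse = ", ")), "variables")
  # monotone visit order: least missing first
  to_impute <- to_impute[order(mis_frac[to_impute])]

  set.seed(config$seed)
  mis_idx <- lapply(to_impute, function(v) is.na(p[[v]]))
  names(mis_idx) <- to_impute

  lapply(seq_len(config$m_imputations), function(i) {
    dat <- p
    # initialise by sampling observed values
    for (v in to_impute) {
      obs_vals <- dat[[v]][!mis_idx[[v]]]
      dat[[v]][mis_idx[[v]]] <- sample(obs_vals, sum(mis_idx[[v]]),
                                       replace = TRUE)
    }
    for (it in seq_len(config$iterations)) {
      for (v in to_impute) {
        rhs <- c(config$predictors, setdiff(vars, v))
        dat[[v]][mis_idx[[v]]] <- pmm_draw(dat, v, rhs, mis_idx[[v]],
                                           config$donors_k)
      }
    }
    if (all(c("cost_0_6", "cost_6_12") %in% names(dat))) {
      dat$cost_excl_intervention <- dat$cost_0_6 + dat$cost_6_12
      dat$cost_total <- dat$cost_excl_intervention + dat$cost_intervention
    }
    if (all(c("qaly_cyp", "qaly_caregiver") %in% names(dat)))
      dat$qaly_combined <- combine_qalys(dat$qaly_cyp, dat$qaly_caregiver)
    out <- dataset
    out$participants <- dat
    out
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' `q_bar` is the mean estimate, `w_bar` the mean within-imputation
#' variance, `b_var` the between-imputation sample variance, and
#' `total_var = w_bar + (1 + 1/m) b_var`. Interval and p-value use the
#' small-sample degrees of freedom
#' `df = (m - 1) (1 + w_bar / ((1 + 1/m) b_var))^2`.
#'
#' @param estimates Numeric vector of per-imputation estimates (length m).
#' @param variances Their squared standard errors.
#' @param conf_level Confidence level.
#' @return A `pooled_estimate` with fields `q_bar`, `w_bar`, `b_var`,
#'   `total_var`, `df`, `ci_low`, `ci_high`, `p_value`, `m`.
#' @examples
#' pool_rubin(c(1, 3), c(1, 1))$total_var  # 4
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) abort_config("Rubin pooling needs m >= 2", "estimates")
  if (length(variances) != m)
    abort_config("`estimates` and `variances` must have equal length",
                 "variances")
  if (any(variances <= 0))
    abort_config("`variances` must be > 0", "variances")
  q_bar <- mean(estimates)
  w_bar <- mean(variances)
  b_var <- var(estimates)
  total_var <- w_bar + (1 + 1 / m) * b_var
  df <- if (b_var > 0) (m - 1) * (1 + w_bar / ((1 + 1 / m) * b_var))^2
        else Inf
  se <- sqrt(total_var)
  tq <- qt(1 - (1 - conf_level) / 2, df)
  structure(list(q_bar = q_bar, w_bar = w_bar, b_var = b_var,
                 total_var = total_var, df = df, m = m,
                 ci_low = q_bar - tq * se, ci_high = q_bar + tq * se,
                 p_value = 2 * stats::pt(-abs(q_bar / se), df)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> m = %d, df = %.1f\n", x$m, x$df))
  cat(sprintf("  %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
              x$q_bar, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Adjusted difference pooled over imputed datasets
#'
#' Fits [adjusted_difference()] on each completed dataset and pools by
#' [pool_rubin()].
#'
#' @param imputed List of completed `trial_dataset`s from
#'   [impute_chained()].
#' @param spec An [adjustment_spec()].
#' @return A `pooled_estimate`.
#' @export
pooled_difference <- function(imputed, spec) {
  fits <- lapply(imputed, adjusted_difference, spec = spec, quiet = TRUE)
  pool_rubin(vapply(fits, `[[`, numeric(1), "estimate"),
             vapply(fits, `[[`, numeric(1), "se")^2)
}

#' CEAC under multiple imputation
#'
#' Default (`"nested_bootstrap"`): the arm-stratified bootstrap of
#' [bootstrap_incrementals()] is run *within* each completed dataset
#' (roughly `B/m` replicates each, seeds derived from the master seed), the
#' replicate clouds are pooled into one joint incremental distribution —
#' preserving the (dCost, dEffect) dependence while propagating imputation
#' uncertainty — and a single CEAC is computed. The alternative
#' (`"rubin_nmb"`) fits, at every willingness-to-pay value, an adjusted
#' regression of participant-level net monetary benefit per imputation,
#' pools by Rubin's rules and converts the pooled z-score to a probability.
#'
#' @param imputed List (length m >= 2) of completed `trial_dataset`s.
#' @param cost_spec,effect_spec [adjustment_spec()]s.
#' @param grid A [wtp_grid()].
#' @param B Total bootstrap replicates across imputations (must be >= m).
#' @param seed Master seed.
#' @param effect_direction As in [bootstrap_incrementals()].
#' @param method `"nested_bootstrap"` or `"rubin_nmb"`.
#' @return A `ceac_curve` (with the pooled incremental distribution in the
#'   `"distribution"` attribute); its `method` field records the engine.
#' @export
ceac_under_mi <- function(imputed, cost_spec, effect_spec,
                          grid = default_wtp_grid("qaly"), B = 1000,
                          seed = 1L,
                          effect_direction = c("higher_better",
                                               "lower_better"),
                          method = c("nested_bootstrap", "rubin_nmb")) {
  method <- match.arg(method)
  effect_direction <- match.arg(effect_direction)
  m <- length(imputed)
  if (m < 2) abort_config("need at least 2 imputed datasets", "imputed")
  if (!inherits(grid, "wtp_grid")) grid <- wtp_grid(grid)
  sgn <- if (effect_direction == "lower_better") -1 else 1

  # Rubin-pooled point estimates of the incremental pair
  pc <- pooled_difference(imputed, cost_spec)
  pe <- pooled_difference(imputed, effect_spec)
  point <- c(delta_cost = pc$q_bar, delta_effect = sgn * pe$q_bar)

  if (method == "nested_bootstrap") {
    if (B < m) abort_config("`B` must be at least the number of imputations",
                            "B")
    b_each <- diff(round(seq(0, B, length.out = m + 1)))
    clouds <- lapply(seq_len(m), function(i) {
      bootstrap_incrementals(imputed[[i]], cost_spec, effect_spec,
                             B = b_each[i], seed = seed + i,
                             effect_direction = effect_direction)$replicates
    })
    dist <- structure(list(replicates = dplyr::bind_rows(clouds),
                           B = B, seed = seed, n_redrawn = 0L,
                           effect_label = effect_spec$outcome,
                           point = point),
                      class = "incremental_distribution")
    out <- ceac(dist, grid)
  } else {
    covs <- union(cost_spec$baseline_covariates,
                  effect_spec$baseline_covariates)
    nmb_spec <- adjustment_spec(
      "nmb", baseline_covariates = covs,
      minimisation_factors = cost_spec$minimisation_factors,
      cluster = cost_spec$cluster, estimator = cost_spec$estimator)
    prob <- vapply(grid$values, function(l) {
      fits <- lapply(imputed, function(ds) {
        p <- ds$participants
        p$nmb <- net_monetary_benefit(sgn * p[[effect_spec$outcome]],
                                      p[[cost_spec$outcome]], l)
        fit_arm_effect(p, nmb_spec, quiet = TRUE)
      })
      pooled <- pool_rubin(vapply(fits, `[[`, numeric(1), "estimate"),
                           vapply(fits, `[[`, numeric(1), "se")^2)
      pnorm(pooled$q_bar / sqrt(pooled$total_var))
    }, numeric(1))
    cross <- grid$values[prob >= 0.5]
    dist <- structure(list(replicates = tibble::tibble(delta_cost = numeric(0),
                                                       delta_effect = numeric(0)),
                           B = 0L, seed = seed, n_redrawn = 0L,
                           effect_label = effect_spec$outcome, point = point),
                      class = "incremental_distribution")
    out <- structure(list(
      curve = tibble::tibble(wtp = grid$values, probability = prob),
      crossing_lambda = if (length(cross)) cross[1] else NA_real_,
      effect_label = grid$effect_label, B = 0L),
      class = "ceac_curve")
  }
  out$method <- method
  attr(out, "distribution") <- dist
  out
}
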