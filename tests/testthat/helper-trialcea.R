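# Shared fixtures, all generated in code.

# A small, fast trial configuration for structural tests.
small_config <- function(n = 80, seed = 42, ...) {
  trial_config(n_participants = n,
               allocation = c(intervention = n / 2, control = n / 2),
               n_sites = 4, seed = seed, ...)
}

# A costed, QALY-augmented small dataset.
small_dataset <- function(n = 80, seed = 42, ...) {
  add_qalys(cost_trial(generate_trial(small_config(n, seed, ...))))
}

# Hand-rolled sample skewness.
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# Fine-grid numerical integrator for a piecewise-linear utility trajectory
# over one year: the independent oracle for the trapezoid QALY.
qaly_numeric_oracle <- function(u0, u6, u12, n_grid = 2001) {
  t <- seq(0, 1, length.out = n_grid)
  u <- approx(x = c(0, 0.5, 1), y = c(u0, u6, u12), xout = t)$y
  sum((u[-1] + u[-n_grid]) / 2) * (t[2] - t[1])
}

# Minimal OLS adjustment spec without covariates, for tiny toy datasets.
bare_spec <- function(outcome) {
  adjustment_spec(outcome, baseline_covariates = character(0),
                  minimisation_factors = character(0),
                  estimator = "ols_fallback")
}

# Tiny two-per-arm toy dataset for exhaustive bootstrap enumeration.
toy4 <- function() {
  tibble::tibble(
    participant_id = paste0("T", 1:4),
    arm = factor(c("control", "control", "intervention", "intervention"),
                 levels = c("control", "intervention")),
    site_id = factor(rep(1, 4)),
    eff = c(0, 2, 1, 5),
    cost = c(10, 20, 30, 60))
}
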