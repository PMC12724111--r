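#' Write a trial dataset to CSV files with a YAML sidecar
#'
#' Writes `participants.csv` (wide, one row per participant, UTF-8,
#' comma-separated with a header row), `service_use.csv` (long records:
#' `participant_id, period, category, quantity`) and `config.yaml` holding
#' the full generator configuration including the seed, so a run can be
#' reproduced exactly.
#'
#' @param dataset A `trial_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("participants.csv", "service_use.csv",
                            "config.yaml"))
  write.csv(dataset$participants, paths[1], row.names = FALSE)
  write.csv(dataset$service_use, paths[2], row.names = FALSE)
  yaml::write_yaml(config_as_yaml(dataset$config), paths[3])
  invisible(paths)
}

config_as_yaml <- function(config) {
  out <- unclass(config)
  out$allocation <- as.list(out$allocation)
  out$baseline_cost_mean <- as.list(out$baseline_cost_mean)
  out$mar_coef <- as.list(out$mar_coef)
  out$missingness <- lapply(out$missingness, as.list)
  out
}

#' Read a trial dataset written by [write_trial()]
#'
#' @param dir Directory holding `participants.csv`, `service_use.csv` and
#'   `config.yaml`.
#' @return A `trial_dataset` with factor codings restored.
#' @export
read_trial <- function(dir) {
  p <- tibble::as_tibble(read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE))
  su <- tibble::as_tibble(read.csv(file.path(dir, "service_use.csv"),
                                   stringsAsFactors = FALSE))
  raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- trial_config(
    n_participants = raw$n_participants,
    allocation = unlist(raw$allocation),
    n_sites = raw$n_sites,
    effect_sdq_6m = raw$effect_sdq_6m, effect_sdq_12m = raw$effect_sdq_12m,
    effect_qaly_cyp = raw$effect_qaly_cyp,
    effect_qaly_caregiver = raw$effect_qaly_caregiver,
    effect_cost_excl_intervention = raw$effect_cost_excl_intervention,
    baseline_cost_mean = unlist(raw$baseline_cost_mean),
    followup_cost_mean_control = raw$followup_cost_mean_control,
    baseline_cost_coef = raw$baseline_cost_coef,
    cost_shape = raw$cost_shape,
    sdq_mean_baseline = raw$sdq_mean_baseline,
    sdq_trend_control = unlist(raw$sdq_trend_control),
    sdq_between_sd = raw$sdq_between_sd, sdq_within_sd = raw$sdq_within_sd,
    utility_means = lapply(raw$utility_means, unlist),
    utility_between_sd = raw$utility_between_sd,
    utility_within_sd = raw$utility_within_sd,
    utility_range = unlist(raw$utility_range),
    site_sd = raw$site_sd,
    session_range = unlist(raw$session_range),
    session_mean = raw$session_mean,
    cost_per_session = raw$cost_per_session,
    missingness = lapply(raw$missingness, unlist),
    missingness_mechanism = raw$missingness_mechanism,
    mar_coef = unlist(raw$mar_coef),
    seed = raw$seed)
  p$arm <- factor(p$arm, levels = c("control", "intervention"))
  p$site_id <- factor(p$site_id, levels = seq_len(cfg$n_sites))
  p$disorder <- factor(p$disorder,
                       levels = c("anxiety", "depression", "disruptive"))
  for (f in c("asd", "intellectual_disability"))
    p[[f]] <- factor(p[[f]], levels = c("no", "yes"))
  p$age_group <- factor(p$age_group, levels = c("<11", ">=11"))
  structure(list(participants = p, service_use = su, config = cfg),
            class = "trial_dataset")
}

#' Simulate a trial and write it to disk
#'
#' Convenience wrapper chaining [generate_trial()], [cost_trial()],
#' [add_qalys()], [apply_missingness()] and [write_trial()].
#'
#' @param config A [trial_config()].
#' @param dir Output directory.
#' @param mask Apply the configured missingness (default `TRUE`).
#' @return Invisibly, the written `trial_dataset`.
#' @export
simulate_to_csv <- function(config, dir, mask = TRUE) {
  ds <- generate_trial(config)
  ds <- cost_trial(ds)
  ds <- add_qalys(ds)
  if (mask) ds <- apply_missingness(ds, config)
  write_trial(ds, dir)
  invisible(ds)
}
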