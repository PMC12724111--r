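#' QALYs from a utility trajectory by trapezoidal area under the curve
#'
#' Integrates a health-utility trajectory measured at 0, 6 and 12 months
#' over the 1-year horizon, assuming linear change between measurement
#' occasions: `qaly = 0.5 * (u0 + u6) / 2 + 0.5 * (u6 + u12) / 2`. The
#' result is complete only when all three utilities are observed; no
#' interpolation over missing occasions is attempted (complete-case rule).
#'
#' @param u0,u6,u12 Utility scores at baseline, 6 and 12 months; vectors are
#'   accepted and recycled to common length. `NA` marks unobserved.
#' @param range Admissible utility interval, default `c(0, 1)` (0 = dead,
#'   1 = perfect health). Use `c(-0.594, 1)` to admit worse-than-dead
#'   EQ-5D-5L states.
#' @return Numeric QALY vector over the 1-year horizon; `NA` where any
#'   constituent utility is missing. Values outside `range` are an error.
#' @examples
#' qaly_auc(0.8, 0.6, 0.7)  # 0.675
#' @export
qaly_auc <- function(u0, u6, u12, range = c(0, 1)) {
  u <- cbind(u0, u6, u12)
  obs <- u[!is.na(u)]
  if (length(obs) && (any(obs < range[1]) || any(obs > range[2])))
    abort_config(sprintf("utilities must lie in [%g, %g]", range[1], range[2]),
                 "utilities")
  unname(0.5 * (u[, 1] + u[, 2]) / 2 + 0.5 * (u[, 2] + u[, 3]) / 2)
}

#' Combine child and caregiver QALYs
#'
#' Total QALY gain across the dyad: the arithmetic sum of the two
#' individual QALYs, missing if either constituent is missing.
#'
#' @param qaly_cyp,qaly_caregiver QALY vectors.
#' @return Their elementwise sum.
#' @export
combine_qalys <- function(qaly_cyp, qaly_caregiver) {
  qaly_cyp + qaly_caregiver
}

#' Look up an SDQ endpoint
#'
#' Returns the recorded SDQ total difficulties score at the requested
#' follow-up; no interpolation, `NA` propagates as the missing marker.
#'
#' @param sdq_series Numeric vector/matrix of scores ordered (0, 6, 12)
#'   months, or a data frame with columns `sdq_0`, `sdq_6`, `sdq_12`.
#' @param month Requested timepoint, 6 or 12.
#' @return The recorded value(s) at that timepoint.
#' @export
sdq_endpoint <- function(sdq_series, month) {
  if (!month %in% c(6, 12))
    abort_config("`month` must be 6 or 12", "month")
  if (is.data.frame(sdq_series))
    return(sdq_series[[paste0("sdq_", month)]])
  idx <- if (month == 6) 2L else 3L
  if (is.matrix(sdq_series)) sdq_series[, idx] else sdq_series[[idx]]
}

#' Add QALY columns to a trial dataset
#'
#' Computes `qaly_cyp`, `qaly_caregiver` (trapezoidal AUC over the observed
#' utility trajectories) and `qaly_combined` (their sum) on the participants
#' table. A QALY is `NA` whenever any of its three utilities is unobserved.
#'
#' @param dataset A `trial_dataset`.
#' @param range Admissible utility interval passed to [qaly_auc()].
#' @return The dataset with QALY columns attached.
#' @export
add_qalys <- function(dataset, range = dataset$config$utility_range %||% c(0, 1)) {
  stopifnot(inherits(dataset, "trial_dataset"))
  p <- dataset$participants
  p$qaly_cyp <- qaly_auc(p$utility_cyp_0, p$utility_cyp_6, p$utility_cyp_12,
                         range = range)
  p$qaly_caregiver <- qaly_auc(p$utility_caregiver_0, p$utility_caregiver_6,
                               p$utility_caregiver_12, range = range)
  p$qaly_combined <- combine_qalys(p$qaly_cyp, p$qaly_caregiver)
  dataset$participants <- p
  dataset
}
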