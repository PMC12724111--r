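#' Micro-costing model for a sessional complex intervention
#'
#' Describes the cost drivers of a therapist-delivered modular intervention:
#' the delivery band's cost per working hour (salary, on-costs, overheads),
#' face-to-face time per session inflated by an indirect-to-face activity
#' ratio (preparation, supervision attendance, administration), supervision
#' time from senior bands, and a training cost amortised equally over a
#' cohort of participants. Supervision and training are converted to a
#' per-session share using a reference number of sessions per participant.
#'
#' The default values form a synthetic illustrative decomposition (they are
#' not published national figures) chosen to yield GBP 80.41 per session at
#' the defaults: GBP 40/h delivery, 1 face-to-face hour per session, ratio
#' 0.75, 2.5 supervision hours per participant at GBP 55/h, GBP 8677
#' training amortised over 166 participants, 18.23 reference sessions.
#'
#' @param therapist_cost_per_hour Delivery-band cost per working hour (GBP).
#' @param supervisor_cost_per_hour Supervising-band cost per hour (GBP).
#' @param face_to_face_hours_per_session Direct contact hours per session.
#' @param indirect_to_face_ratio Indirect hours per face-to-face hour (>= 0).
#' @param supervision_hours_per_participant Supervision hours attributable to
#'   one participant's course of therapy.
#' @param training_cost_total Total training cost (GBP) to amortise.
#' @param training_amortisation_n Participants over which training is spread.
#' @param sessions_reference Sessions per participant used to convert
#'   per-participant overheads into a per-session share.
#' @param scaling_factor In `(0, 1]`; 1 = the intervention is fully
#'   additional to usual care, 0.75 = a quarter of its cost substitutes for
#'   standard service activity.
#' @return An object of class `intervention_cost_model`.
#' @export
intervention_cost_model <- function(therapist_cost_per_hour = 40,
                                    supervisor_cost_per_hour = 55,
                                    face_to_face_hours_per_session = 1,
                                    indirect_to_face_ratio = 0.75,
                                    supervision_hours_per_participant = 2.5,
                                    training_cost_total = 8677,
                                    training_amortisation_n = 166,
                                    sessions_reference = 18.23,
                                    scaling_factor = 1) {
  m <- list(therapist_cost_per_hour = therapist_cost_per_hour,
            supervisor_cost_per_hour = supervisor_cost_per_hour,
            face_to_face_hours_per_session = face_to_face_hours_per_session,
            indirect_to_face_ratio = indirect_to_face_ratio,
            supervision_hours_per_participant = supervision_hours_per_participant,
            training_cost_total = training_cost_total,
            training_amortisation_n = training_amortisation_n,
            sessions_reference = sessions_reference,
            scaling_factor = scaling_factor)
  for (f in c("therapist_cost_per_hour", "supervisor_cost_per_hour",
              "supervision_hours_per_participant", "training_cost_total",
              "indirect_to_face_ratio"))
    if (m[[f]] < 0) abort_config(sprintf("`%s` must be >= 0", f), f)
  if (m$face_to_face_hours_per_session <= 0)
    abort_config("`face_to_face_hours_per_session` must be > 0",
                 "face_to_face_hours_per_session")
  if (m$training_amortisation_n < 1)
    abort_config("`training_amortisation_n` must be >= 1",
                 "training_amortisation_n")
  if (m$sessions_reference <= 0)
    abort_config("`sessions_reference` must be > 0", "sessions_reference")
  if (m$scaling_factor <= 0 || m$scaling_factor > 1)
    abort_config("`scaling_factor` must be in (0, 1]", "scaling_factor")
  structure(m, class = "intervention_cost_model")
}

#' Cost per delivered session, with auditable components
#'
#' @param model An [intervention_cost_model()].
#' @return A list with `staff_delivery` (face-to-face plus indirect staff
#'   time), `supervision_share`, `training_share` and their sum `total`, all
#'   GBP per session, unscaled (the substitution `scaling_factor` applies to
#'   participant totals, not the per-session price).
#' @examples
#' m <- intervention_cost_model()
#' round(cost_intervention_session(m)$total, 2)  # 80.41 at the defaults
#' @export
cost_intervention_session <- function(model) {
  stopifnot(inherits(model, "intervention_cost_model"))
  staff <- model$therapist_cost_per_hour *
    model$face_to_face_hours_per_session * (1 + model$indirect_to_face_ratio)
  supervision <- model$supervision_hours_per_participant *
    model$supervisor_cost_per_hour / model$sessions_reference
  training <- model$training_cost_total / model$training_amortisation_n /
    model$sessions_reference
  list(staff_delivery = staff, supervision_share = supervision,
       training_share = training, total = staff + supervision + training)
}

#' Per-participant intervention cost
#'
#' Sessions attended times the per-session cost, then multiplied by the
#' model's substitution `scaling_factor`. Zero sessions (the control arm)
#' cost zero regardless of the model.
#'
#' @param sessions_attended Nonnegative session count (fractional values are
#'   accepted for arm-mean calculations).
#' @param model An [intervention_cost_model()].
#' @return Cost in GBP (vectorised over `sessions_attended`).
#' @export
cost_intervention_total <- function(sessions_attended, model) {
  if (any(sessions_attended < 0))
    abort_config("`sessions_attended` must be >= 0", "sessions_attended")
  sessions_attended * cost_intervention_session(model)$total *
    model$scaling_factor
}

#' Price service-use records against a unit-cost table
#'
#' Multiplies each record's quantity by its category unit cost and sums
#' within participant-period-category. Participants supplied via
#' `participants` but absent from `records` receive explicit zero-cost rows
#' (zero use is data, not missingness). Unknown categories are an error
#' naming the category and the participants affected.
#'
#' @param records Data frame with columns `participant_id`, `period`,
#'   `category`, `quantity` (>= 0).
#' @param table A [unit_cost_table()].
#' @param participants Optional character vector of participant ids defining
#'   the costing frame; defaults to the ids present in `records`.
#' @param periods Optional period labels for the frame; defaults to those in
#'   `records`.
#' @return A tibble of class `cost_breakdown`: `participant_id`, `period`,
#'   `category`, `quantity`, `unit_cost`, `cost`, including zero rows, plus
#'   the per-participant-period totals via [service_cost_totals()].
#' @examples
#' uc <- default_unit_costs()
#' rec <- data.frame(participant_id = "P1", period = "m0_6",
#'                   category = "gp", quantity = 2)
#' service_cost_totals(cost_service_use(rec, uc))$cost  # 2 x 39 = 78
#' @export
cost_service_use <- function(records, table, participants = NULL,
                             periods = NULL) {
  records <- tibble::as_tibble(records)
  req <- c("participant_id", "period", "category", "quantity")
  if (!all(req %in% names(records)))
    abort_config(sprintf("`records` needs columns: %s",
                         paste(req, collapse = ", ")), "records")
  if (nrow(records) && any(records$quantity < 0))
    abort_config("service-use quantities must be >= 0", "records")
  if (nrow(records)) {
    known <- table$entries$category
    bad <- !(records$category %in% known)
    if (any(bad)) {
      unit_cost_lookup(table, records$category[bad],
                       participant = records$participant_id[bad])
    }
  }
  participants <- participants %||% unique(records$participant_id)
  periods <- periods %||% unique(records$period)
  if (!length(periods)) periods <- "all"

  agg <- records |>
    dplyr::group_by(.data$participant_id, .data$period, .data$category) |>
    dplyr::summarise(quantity = sum(.data$quantity), .groups = "drop")
  frame <- tidyr::expand_grid(participant_id = participants, period = periods,
                              category = table$entries$category)
  out <- dplyr::left_join(frame, agg,
                          by = c("participant_id", "period", "category")) |>
    dplyr::mutate(quantity = dplyr::coalesce(.data$quantity, 0),
                  unit_cost = unit_cost_lookup(table, .data$category),
                  cost = .data$quantity * .data$unit_cost)
  class(out) <- c("cost_breakdown", class(out))
  out
}

#' Total cost per participant-period from a cost breakdown
#'
#' @param breakdown A `cost_breakdown` from [cost_service_use()].
#' @return Tibble `participant_id`, `period`, `cost` (exact category sums).
#' @export
service_cost_totals <- function(breakdown) {
  breakdown |>
    dplyr::group_by(.data$participant_id, .data$period) |>
    dplyr::summarise(cost = sum(.data$cost), .groups = "drop")
}

#' Attach costs to a trial dataset
#'
#' Re-prices the dataset's service-use records with `table`, costs the
#' intervention exposure with `model`, and writes the participant-level cost
#' columns (`cost_baseline`, `cost_0_6`, `cost_6_12`, `cost_intervention`,
#' `cost_excl_intervention`, `cost_total`). Periods flagged unobserved stay
#' `NA`; control-arm intervention cost is identically zero.
#'
#' @param dataset A `trial_dataset`.
#' @param table A [unit_cost_table()]; defaults to the bundled synthetic one.
#' @param model An [intervention_cost_model()]; its `scaling_factor` is
#'   applied to the intervention component of `cost_total`.
#' @return The dataset with refreshed cost columns.
#' @export
cost_trial <- function(dataset, table = default_unit_costs(),
                       model = intervention_cost_model()) {
  stopifnot(inherits(dataset, "trial_dataset"))
  p <- dataset$participants
  totals <- service_cost_totals(
    cost_service_use(dataset$service_use, table,
                     participants = p$participant_id,
                     periods = c("baseline_3m", "m0_6", "m6_12"))) |>
    tidyr::pivot_wider(names_from = "period", values_from = "cost")
  totals <- totals[match(p$participant_id, totals$participant_id), ]
  p$cost_baseline <- totals$baseline_3m
  p$cost_0_6 <- ifelse(p$obs_cost_6, totals$m0_6, NA_real_)
  p$cost_6_12 <- ifelse(p$obs_cost_12, totals$m6_12, NA_real_)
  # store the full (unscaled) component; scaling enters the total only
  p$cost_intervention <- p$sessions_attended *
    cost_intervention_session(model)$total
  p$cost_excl_intervention <- p$cost_0_6 + p$cost_6_12
  p$cost_total <- p$cost_excl_intervention +
    model$scaling_factor * p$cost_intervention
  dataset$participants <- p
  dataset
}

#' Scale the intervention cost component
#'
#' Applies a substitution scenario: only the intervention component is
#' scaled; costs excluding the intervention are untouched and totals are
#' recomputed. Works on a `trial_dataset` or on any data frame carrying
#' `cost_excl_intervention`, `cost_intervention` and `cost_total` columns.
#'
#' @param x Object holding cost components.
#' @param factor Scaling factor in `(0, 1]` (0.75 = 75%-cost scenario).
#' @return `x` with `cost_total = cost_excl_intervention + factor *
#'   cost_intervention`.
#' @export
scale_intervention <- function(x, factor) {
  if (length(factor) != 1 || is.na(factor) || factor <= 0 || factor > 1)
    abort_config("`factor` must be a single value in (0, 1]", "factor")
  UseMethod("scale_intervention")
}

#' @export
scale_intervention.trial_dataset <- function(x, factor) {
  x$participants <- scale_intervention(x$participants, factor)
  x
}

#' @export
scale_intervention.data.frame <- function(x, factor) {
  req <- c("cost_excl_intervention", "cost_intervention", "cost_total")
  if (!all(req %in% names(x)))
    abort_config(sprintf("`x` needs columns: %s", paste(req, collapse = ", ")),
                 "x")
  x$cost_total <- x$cost_excl_intervention + factor * x$cost_intervention
  x
}

#' Round to whole pence for reporting
#'
#' Half-even (banker's) rounding to GBP 0.01; all internal arithmetic is
#' kept at full double precision and rounded only when tables are written.
#' @param x Numeric GBP values.
#' @return `x` rounded to 2 decimal places.
#' @export
round_gbp <- function(x) round(x, 2)
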