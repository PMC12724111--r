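#' Unit-cost tables
#'
#' A unit-cost table maps service categories to a cost per unit of use
#' (contact, night, or prescription item-month). All pricing in the package
#' goes through such a table; no national unit costs are hard-coded into the
#' costing functions themselves.
#'
#' @param entries A data frame (or tibble) with columns `category`, `unit`
#'   (one of `"contact"`, `"night"`, `"item"`), `unit_cost` (GBP, >= 0) and
#'   optionally `source`.
#' @param currency_year Label for the price year, e.g. `"2020/21"`.
#' @return An object of class `unit_cost_table`.
#' @seealso [default_unit_costs()], [read_unit_cost_table()]
#' @export
unit_cost_table <- function(entries, currency_year = "2020/21") {
  entries <- tibble::as_tibble(entries)
  req <- c("category", "unit", "unit_cost")
  if (!all(req %in% names(entries)))
    abort_config(sprintf("unit-cost entries need columns: %s",
                         paste(req, collapse = ", ")), "entries")
  if (anyDuplicated(entries$category))
    abort_config("unit-cost categories must be unique", "entries")
  if (any(entries$unit_cost < 0))
    abort_config("unit costs must be >= 0", "entries")
  bad <- setdiff(unique(entries$unit), c("contact", "night", "item"))
  if (length(bad))
    abort_config(sprintf("unknown unit(s): %s", paste(bad, collapse = ", ")),
                 "entries")
  structure(list(entries = entries, currency_year = currency_year),
            class = "unit_cost_table")
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat(sprintf("<unit_cost_table> %d categories, %s prices\n",
              nrow(x$entries), x$currency_year))
  print(x$entries, n = 6)
  invisible(x)
}

#' Synthetic default unit-cost table
#'
#' A bundled, clearly synthetic set of UK-flavoured 2020/21 unit costs
#' covering the service categories the generator emits (out-patient,
#' in-patient, emergency, primary/community care, mental-health services and
#' per-prescription-month medication categories). Values are plausible
#' round figures for illustration and testing; real analyses should supply
#' their own table via [read_unit_cost_table()].
#'
#' @return A `unit_cost_table`.
#' @export
default_unit_costs <- function() {
  path <- system.file("extdata", "unit_costs_synthetic.csv",
                      package = "trialcea", mustWork = TRUE)
  read_unit_cost_table(path)
}

#' Read a unit-cost table from CSV
#'
#' Expected columns: `category, unit, unit_cost[, source, year]`. The `year`
#' column (if present and constant) becomes the table's currency-year label.
#'
#' @param path CSV file path.
#' @param currency_year Optional override for the currency-year label.
#' @return A `unit_cost_table`.
#' @export
read_unit_cost_table <- function(path, currency_year = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  year <- currency_year %||%
    (if ("year" %in% names(df)) as.character(df$year[1]) else "unspecified")
  unit_cost_table(df[setdiff(names(df), "year")], currency_year = year)
}

# Named cost lookup vector, error on request for unknown categories.
unit_cost_lookup <- function(table, categories, participant = NULL) {
  stopifnot(inherits(table, "unit_cost_table"))
  costs <- setNames(table$entries$unit_cost, table$entries$category)
  unknown <- setdiff(unique(categories), names(costs))
  if (length(unknown)) {
    who <- if (is.null(participant)) "" else sprintf(" (participant %s)",
                                                     paste(unique(participant), collapse = ", "))
    stop(sprintf("service categor%s not in unit-cost table%s: %s",
                 if (length(unknown) > 1) "ies" else "y", who,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  costs[categories]
}

# Expected long-run share of total cost by category, used by the generator
# to decompose a target period cost into service quantities. Weights sum
# to 1; in-patient categories dominate, as in real paediatric cost data.
generator_cost_shares <- function() {
  c(inpatient_epilepsy      = 0.22,
    inpatient_other         = 0.18,
    outpatient_epilepsy     = 0.16,
    outpatient_other        = 0.10,
    outpatient_mental_health = 0.03,
    a_and_e                 = 0.05,
    ambulance               = 0.03,
    gp                      = 0.04,
    community_nurse         = 0.05,
    community_paediatrician = 0.04,
    camhs                   = 0.03,
    clinical_psychologist   = 0.02,
    counselling             = 0.01,
    medication_epilepsy     = 0.02,
    medication_other        = 0.01,
    medication_mental_health = 0.01)
}
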