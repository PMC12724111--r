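#' Read an intervention cost model from YAML
#'
#' The YAML file holds the fields of [intervention_cost_model()] by name.
#' A bundled synthetic example (`intervention_cost_synthetic.yaml` under
#' `extdata`) illustrates a decomposition that prices a session at
#' GBP 80.41.
#'
#' @param path YAML file; defaults to the bundled synthetic model.
#' @return An [intervention_cost_model()].
#' @export
read_intervention_model <- function(path = system.file(
  "extdata", "intervention_cost_synthetic.yaml", package = "trialcea",
  mustWork = TRUE)) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(intervention_cost_model))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort_config(paste("unknown intervention-model field(s):",
                       paste(unknown, collapse = ", ")), "path")
  do.call(intervention_cost_model, vals)
}
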