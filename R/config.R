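#' Read priors and cohort presets from a YAML configuration file
#'
#' The file may contain any of three top-level blocks:
#' \preformatted{
#' generative:
#'   typical_improvement_mean: 0.44
#'   typical_improvement_sd: 0.40
#'   ate_mean: 0.30
#'   ate_sd: 0.27
#'   heterogeneous_response_sd: 0.15
#'   measurement_error_sd: 0.20
#' fitting:
#'   mean: 0
#'   sd: 0.40
#'   variance_prior: jeffreys
#' presets:
#'   - outcome_name: elbow_flexor_55
#'     pre_mean: 39.6
#'     pre_sd: 8.6
#'     unit: mm
#' }
#' Omitted blocks fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `generative` ([generative_priors()]),
#'   `fitting` ([fitting_prior()]), and `presets` (named list of
#'   [cohort_preset()]; the bundled [cohort_presets()] when absent).
#' @export
read_priors_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  generative <- if (is.null(cfg$generative)) generative_priors()
                else do.call(generative_priors, cfg$generative)
  fitting <- if (is.null(cfg$fitting)) fitting_prior()
             else do.call(fitting_prior, cfg$fitting)
  presets <- if (is.null(cfg$presets)) cohort_presets()
             else {
               p <- lapply(cfg$presets, function(x) do.call(cohort_preset, x))
               names(p) <- vapply(p, `[[`, "", "outcome_name")
               p
             }
  list(generative = generative, fitting = fitting, presets = presets)
}
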