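#' Generative priors for prior-predictive simulation
#'
#' Bundles the four standardized-scale distributions that define the
#' prior-predictive data model for a two-condition within-participant trial:
#' the typical improvement common to both limbs, the average treatment effect
#' (ATE) of the intervention condition, the heterogeneous response of each
#' limb, and measurement error.  All values are on a standardized (baseline
#' SD) scale.  The defaults are informative values drawn from meta-analyses of
#' hypertrophy and strength-and-conditioning effect distributions: typical
#' improvement N(0.44, 0.40^2), ATE N(0.30, 0.27^2), heterogeneous response
#' N(0, 0.15^2) and measurement error N(0, 0.20^2) per measurement occasion.
#'
#' @param typical_improvement_mean,typical_improvement_sd Mean and SD of the
#'   pre-to-post improvement shared by both conditions (standardized units).
#' @param ate_mean,ate_sd Mean and SD of the average treatment effect, the
#'   condition difference in change scores (standardized units).  Positive
#'   values favour the intervention (full range of motion) condition.
#' @param heterogeneous_response_sd SD of the limb-level response deviation
#'   (standardized units).
#' @param measurement_error_sd SD of measurement error for a single
#'   measurement occasion (standardized units).
#'
#' @return An object of class `generative_priors` (a named list).
#' @seealso [draw_prior_predictive()], [draw_raw_cohort()]
#' @examples
#' generative_priors()
#' generative_priors(ate_mean = 0, ate_sd = 0.1)
#' @export
generative_priors <- function(typical_improvement_mean = 0.44,
                              typical_improvement_sd = 0.40,
                              ate_mean = 0.30,
                              ate_sd = 0.27,
                              heterogeneous_response_sd = 0.15,
                              measurement_error_sd = 0.20) {
  priors <- list(
    typical_improvement_mean = as.numeric(typical_improvement_mean),
    typical_improvement_sd = as.numeric(typical_improvement_sd),
    ate_mean = as.numeric(ate_mean),
    ate_sd = as.numeric(ate_sd),
    heterogeneous_response_sd = as.numeric(heterogeneous_response_sd),
    measurement_error_sd = as.numeric(measurement_error_sd)
  )
  sds <- c("typical_improvement_sd", "ate_sd", "heterogeneous_response_sd",
           "measurement_error_sd")
  for (f in names(priors)) {
    if (length(priors[[f]]) != 1L || !is.finite(priors[[f]]))
      stop("`", f, "` must be a single finite number", call. = FALSE)
  }
  for (f in sds) {
    if (priors[[f]] < 0)
      stop("`", f, "` must be >= 0", call. = FALSE)
  }
  structure(priors, class = "generative_priors")
}

#' @export
print.generative_priors <- function(x, ...) {
  cat("Generative priors (standardized scale)\n")
  cat(sprintf("  typical improvement    : N(%.3g, %.3g^2)\n",
              x$typical_improvement_mean, x$typical_improvement_sd))
  cat(sprintf("  average treatment effect: N(%.3g, %.3g^2)\n",
              x$ate_mean, x$ate_sd))
  cat(sprintf("  heterogeneous response : N(0, %.3g^2)\n",
              x$heterogeneous_response_sd))
  cat(sprintf("  measurement error      : N(0, %.3g^2) per occasion\n",
              x$measurement_error_sd))
  invisible(x)
}

#' Fitting prior for the paired-model average treatment effect
#'
#' Defines the prior used when *fitting* the paired Bayesian model, as opposed
#' to the informative priors used to *generate* data.  The default is the
#' neutral prior N(0, 0.40^2) on the ATE, with the residual change-score
#' variance either treated as unknown (marginalized under a variance prior,
#' the default) or fixed at a known value.
#'
#' @param mean,sd Mean and SD of the normal prior on the average treatment
#'   effect.  `sd` must be positive.
#' @param variance_prior Prior on the unknown change-score variance:
#'   `"jeffreys"` (scale-invariant, proportional to 1/sigma^2; the default),
#'   `"half_normal"` (half-normal on the change-score SD with scale
#'   `variance_scale`), or `"lognormal"` (log-normal on the variance with
#'   parameters `variance_par = c(meanlog, sdlog)`).
#' @param variance_scale Scale of the half-normal prior on the SD (used only
#'   when `variance_prior = "half_normal"`).
#' @param variance_par Length-2 numeric `c(meanlog, sdlog)` for
#'   `variance_prior = "lognormal"` (on the log variance).
#' @param sigma_d Known change-score SD.  When supplied, the model runs in
#'   known-variance mode and the posterior is conjugate normal in closed form.
#'
#' @return An object of class `fitting_prior`.
#' @examples
#' fitting_prior()                  # neutral N(0, 0.40^2), Jeffreys variance
#' fitting_prior(sigma_d = 0.4)     # known-variance mode
#' @export
fitting_prior <- function(mean = 0, sd = 0.40,
                          variance_prior = c("jeffreys", "half_normal",
                                             "lognormal"),
                          variance_scale = 1,
                          variance_par = NULL,
                          sigma_d = NULL) {
  variance_prior <- match.arg(variance_prior)
  if (!is.finite(mean)) stop("`mean` must be finite", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (!is.null(sigma_d) && (!is.finite(sigma_d) || sigma_d <= 0))
    stop("`sigma_d` must be > 0", call. = FALSE)
  if (variance_prior == "half_normal" &&
      (!is.finite(variance_scale) || variance_scale <= 0))
    stop("`variance_scale` must be > 0", call. = FALSE)
  if (variance_prior == "lognormal") {
    if (is.null(variance_par) || length(variance_par) != 2L ||
        !all(is.finite(variance_par)) || variance_par[2] <= 0)
      stop("`variance_par` must be c(meanlog, sdlog) with sdlog > 0",
           call. = FALSE)
  }
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 variance_prior = variance_prior,
                 variance_scale = as.numeric(variance_scale),
                 variance_par = variance_par,
                 sigma_d = if (is.null(sigma_d)) NULL else as.numeric(sigma_d),
                 mode = if (is.null(sigma_d)) "unknown_variance"
                        else "known_variance"),
            class = "fitting_prior")
}

#' @export
print.fitting_prior <- function(x, ...) {
  cat(sprintf("ATE fitting prior: N(%.4g, %.4g^2)\n", x$mean, x$sd))
  if (x$mode == "known_variance") {
    cat(sprintf("  change-score SD known: sigma_d = %.4g\n", x$sigma_d))
  } else {
    cat("  change-score variance unknown, prior:", x$variance_prior, "\n")
  }
  invisible(x)
}

# rescale a standardized-scale fitting prior to raw units
rescale_fitting_prior <- function(prior, scale_sd) {
  stopifnot(is.finite(scale_sd), scale_sd > 0)
  fitting_prior(mean = prior$mean * scale_sd, sd = prior$sd * scale_sd,
                variance_prior = prior$variance_prior,
                variance_scale = prior$variance_scale * scale_sd,
                variance_par = if (is.null(prior$variance_par)) NULL
                  else prior$variance_par + c(2 * log(scale_sd), 0),
                sigma_d = if (is.null(prior$sigma_d)) NULL
                  else prior$sigma_d * scale_sd)
}

#' Synthetic raw-unit cohort preset
#'
#' Describes the baseline distribution of an outcome in raw units so that
#' [draw_raw_cohort()] can produce synthetic cohorts on the scale of real
#' measurements (muscle thickness in mm, 10 RM load in kg).
#'
#' `pre_post_correlation` is optional.  Because post = pre + change and the
#' change-score distribution is fixed by the generative model, the attainable
#' pre/post correlation is bounded below by `sqrt(1 - k^2)` where `k` is the
#' ratio of the conditional change-score SD to the baseline SD; with the
#' default generative priors the bound is about 0.97.  `NULL` (the default)
#' requests the natural value in which the baseline is independent of the
#' change-score residuals, consistent with the near-unity test-retest
#' reliability typical of these measurements.
#'
#' @param outcome_name Label for the outcome (e.g. `"elbow_flexor_55"`).
#' @param pre_mean,pre_sd Baseline mean and SD in raw units; `pre_sd > 0`.
#' @param pre_post_correlation Target correlation between pre and post
#'   measurements, in `[-1, 1]`, or `NULL` for the natural value.
#' @param unit Unit label for the outcome (`"mm"`, `"kg"`, ...).
#'
#' @return An object of class `cohort_preset`.
#' @examples
#' cohort_preset("elbow_flexor_55", pre_mean = 39.6, pre_sd = 8.6)
#' @export
cohort_preset <- function(outcome_name, pre_mean, pre_sd,
                          pre_post_correlation = NULL, unit = "mm") {
  if (!is.character(outcome_name) || length(outcome_name) != 1L)
    stop("`outcome_name` must be a single string", call. = FALSE)
  if (!is.finite(pre_mean)) stop("`pre_mean` must be finite", call. = FALSE)
  if (!is.finite(pre_sd) || pre_sd <= 0)
    stop("`pre_sd` must be > 0", call. = FALSE)
  if (!is.null(pre_post_correlation)) {
    if (!is.finite(pre_post_correlation) || abs(pre_post_correlation) > 1)
      stop("`pre_post_correlation` must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(outcome_name = outcome_name,
                 pre_mean = as.numeric(pre_mean),
                 pre_sd = as.numeric(pre_sd),
                 pre_post_correlation = pre_post_correlation,
                 unit = unit),
            class = "cohort_preset")
}

#' Bundled synthetic cohort presets
#'
#' Presets for the six study outcomes — four upper-arm muscle-thickness sites
#' (elbow flexors and extensors at 45% and 55% of humeral length, mm) and two
#' strength-endurance tests (10 RM lat-pulldown load in full and partial range
#' of motion, kg) — with baseline means and SDs matching the published
#' pre-study descriptives of the reference (partial range of motion)
#' condition.  These drive synthetic fixtures only; no participant data are
#' included.
#'
#' @return A named list of [cohort_preset()] objects.
#' @examples
#' names(cohort_presets())
#' @export
cohort_presets <- function() {
  presets <- list(
    cohort_preset("elbow_flexor_55",   39.6,  8.6, unit = "mm"),
    cohort_preset("elbow_flexor_45",   36.5,  8.9, unit = "mm"),
    cohort_preset("elbow_extensor_55", 35.1,  9.5, unit = "mm"),
    cohort_preset("elbow_extensor_45", 41.5, 10.5, unit = "mm"),
    cohort_preset("ten_rm_full",       63.4, 17.1, unit = "kg"),
    cohort_preset("ten_rm_partial",    66.8, 20.7, unit = "kg")
  )
  names(presets) <- vapply(presets, `[[`, "", "outcome_name")
  presets
}
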