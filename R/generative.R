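#' Simulate a prior-predictive trial dataset on the standardized scale
#'
#' Draws one dataset of 2n change scores for a two-condition
#' within-participant trial from the generative model
#' \deqn{change_{i,c} = \theta + \delta x_c + b_{i,c} + \eta_{i,c},}
#' where the typical improvement \eqn{\theta} and the average treatment
#' effect \eqn{\delta} are drawn once per dataset from their priors (this is
#' a prior-predictive draw over the unknown true effects), the heterogeneous
#' response \eqn{b} is drawn per limb (per participant-condition) by default,
#' and \eqn{\eta} is measurement noise on the change score.  \eqn{x_c} is 0
#' for the reference (pROM) and 1 for the intervention (fROM) condition.
#'
#' Two structural choices are configurable because the change-score noise can
#' be represented at either of two levels:
#' \itemize{
#'   \item `measurement = "change"` (default): one error draw per change
#'     score, \eqn{\eta \sim N(0, \sigma_\epsilon^2)}.
#'   \item `measurement = "pre_post"`: independent errors at the pre and post
#'     occasions which the change score inherits,
#'     \eqn{\eta \sim N(0, 2\sigma_\epsilon^2)}.
#' }
#' and the heterogeneous response can be drawn per limb
#' (`response_per_condition = TRUE`, default) or shared by both limbs of a
#' participant (`FALSE`, in which case it cancels exactly in paired
#' differences).  With the defaults, the paired difference for participant i
#' is \eqn{d_i = \delta + (b_{i,1}-b_{i,0}) + (\eta_{i,1}-\eta_{i,0})} with
#' variance \eqn{2(\sigma_b^2 + \sigma_\epsilon^2)}.  The rationale for these
#' defaults is discussed in the package vignette.
#'
#' @param priors A [generative_priors()] object.
#' @param n Number of participants (at least 2).
#' @param null_effect If `TRUE`, the average treatment effect is fixed at 0
#'   instead of being drawn from its prior (all other components are still
#'   drawn); used for calibration under the null hypothesis.
#' @param response_per_condition Draw the heterogeneous response per limb
#'   (`TRUE`, default) or once per participant (`FALSE`).
#' @param measurement `"change"` (one error per change score, default) or
#'   `"pre_post"` (independent pre and post errors).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so enclosing workflows can seed once).
#'
#' @return A standardized [trial_dataset()].  The realized \eqn{\theta} and
#'   \eqn{\delta} are recorded in the `realized` attribute for recovery
#'   testing.
#' @examples
#' ds <- draw_prior_predictive(generative_priors(), n = 20, seed = 42)
#' attr(ds, "realized")$delta
#' mean(paired_differences(ds))
#' @export
draw_prior_predictive <- function(priors = generative_priors(), n,
                                  null_effect = FALSE,
                                  response_per_condition = TRUE,
                                  measurement = c("change", "pre_post"),
                                  seed = NULL) {
  measurement <- match.arg(measurement)
  if (!inherits(priors, "generative_priors"))
    priors <- do.call(generative_priors, as.list(priors))
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("invalid design: `n` must be an integer >= 2", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  theta <- stats::rnorm(1, priors$typical_improvement_mean,
                        priors$typical_improvement_sd)
  delta <- if (null_effect) 0 else stats::rnorm(1, priors$ate_mean,
                                                priors$ate_sd)
  b <- if (response_per_condition) {
    matrix(stats::rnorm(2L * n, 0, priors$heterogeneous_response_sd), n, 2L)
  } else {
    matrix(stats::rnorm(n, 0, priors$heterogeneous_response_sd), n, 2L)
  }
  eta_sd <- change_noise_sd(priors, measurement)
  eta <- matrix(stats::rnorm(2L * n, 0, eta_sd), n, 2L)
  xc <- matrix(c(0, 1), n, 2L, byrow = TRUE)
  change <- theta + delta * xc + b + eta

  ds <- trial_dataset(
    data.frame(
      participant_id = rep(sprintf("P%03d", seq_len(n)), each = 2L),
      condition = rep(c(0L, 1L), n),
      change = as.vector(t(change))
    ),
    scale = "standardized", unit_label = "SD"
  )
  attr(ds, "realized") <- list(theta = theta, delta = delta)
  attr(ds, "generator") <- list(priors = priors,
                                response_per_condition = response_per_condition,
                                measurement = measurement,
                                null_effect = null_effect)
  ds
}

# SD of the change-score noise term under each measurement representation
change_noise_sd <- function(priors, measurement) {
  switch(measurement,
         change = priors$measurement_error_sd,
         pre_post = sqrt(2) * priors$measurement_error_sd)
}

# SD of a paired difference d_i conditional on theta and delta
conditional_difference_sd <- function(priors, response_per_condition = TRUE,
                                      measurement = "change") {
  eta_var <- change_noise_sd(priors, measurement)^2
  b_var <- if (response_per_condition) priors$heterogeneous_response_sd^2
           else 0
  sqrt(2 * (b_var + eta_var))
}

#' Simulate a raw-unit synthetic cohort
#'
#' Builds a synthetic cohort on the scale of real measurements.  Baselines
#' are drawn around the preset mean with the preset SD; change scores follow
#' the standardized generative model of [draw_prior_predictive()] multiplied
#' by `pre_sd`; `post = pre + change`.  When the preset requests a specific
#' pre/post correlation, the baseline is drawn with exactly the negative (or
#' positive) coupling to the change-score residuals needed to achieve it;
#' because the change distribution and the baseline SD are both fixed, only
#' correlations in `[sqrt(1 - k^2), 1]` are attainable, `k` being the ratio
#' of conditional change SD to baseline SD, and values outside that range
#' raise an error.
#'
#' @param preset A [cohort_preset()].
#' @param priors A [generative_priors()] object.
#' @param n Number of participants.
#' @param seed Optional integer seed.
#' @inheritParams draw_prior_predictive
#'
#' @return A raw-scale [trial_dataset()] with `pre`, `post` and `change`
#'   columns in the preset's units.
#' @examples
#' preset <- cohort_preset("elbow_flexor_55", 39.6, 8.6, unit = "mm")
#' ds <- draw_raw_cohort(preset, n = 25, seed = 7)
#' mean(ds$pre)
#' @export
draw_raw_cohort <- function(preset, priors = generative_priors(), n,
                            null_effect = FALSE,
                            response_per_condition = TRUE,
                            measurement = c("change", "pre_post"),
                            seed = NULL) {
  measurement <- match.arg(measurement)
  if (!inherits(preset, "cohort_preset"))
    stop("`preset` must be a cohort_preset object", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  std <- draw_prior_predictive(priors, n, null_effect = null_effect,
                               response_per_condition = response_per_condition,
                               measurement = measurement, seed = NULL)
  realized <- attr(std, "realized")
  s <- preset$pre_sd
  change_raw <- std$change * s
  mean_change_raw <- (realized$theta + realized$delta * std$condition) * s
  sd_change <- conditional_difference_sd(priors, response_per_condition,
                                         measurement) / sqrt(2) * s
  m <- nrow(std)

  if (sd_change < 1e-12 * s) {
    pre <- stats::rnorm(m, preset$pre_mean, s)
  } else if (is.null(preset$pre_post_correlation)) {
    # natural coupling: baseline independent of the change residuals
    pre <- stats::rnorm(m, preset$pre_mean, s)
  } else {
    r <- solve_pre_change_cor(preset$pre_post_correlation, s, sd_change)
    zc <- (change_raw - mean_change_raw) / sd_change
    pre <- preset$pre_mean + s * (r * zc + sqrt(1 - r^2) * stats::rnorm(m))
  }

  out <- as.data.frame(std)
  out$pre <- pre
  out$post <- pre + change_raw
  out$change <- change_raw
  ds <- trial_dataset(out, scale = "raw", unit_label = preset$unit)
  attr(ds, "realized") <- realized
  attr(ds, "preset") <- preset
  ds
}

# correlation between baseline and change residual needed so that
# cor(pre, pre + change) = rho, given sd(pre) = s and sd(change) = v
solve_pre_change_cor <- function(rho, s, v) {
  f <- function(r) {
    (s^2 + r * s * v) / (s * sqrt(s^2 + v^2 + 2 * r * s * v)) - rho
  }
  k <- v / s
  lo <- sqrt(max(0, 1 - min(k, 1 / k)^2))  # smallest attainable correlation
  if (rho < lo - 1e-12 || rho > 1) {
    stop(sprintf(paste0("pre_post_correlation = %.3f is not attainable: with ",
                        "post = pre + change and the generative change ",
                        "distribution, the correlation must lie in ",
                        "[%.4f, 1]"), rho, lo), call. = FALSE)
  }
  eps <- 1e-12
  if (f(-1 + eps) * f(1 - eps) > 0) {
    # two roots exist (f dips to the minimum and returns); take the branch
    # with the weaker coupling, searching from the minimizer upward
    rmin <- -min(k, 1 / k)
    if (f(rmin) * f(1 - eps) > 0)
      stop("pre_post_correlation is not attainable", call. = FALSE)
    stats::uniroot(f, c(rmin, 1 - eps), tol = 1e-12)$root
  } else {
    stats::uniroot(f, c(-1 + eps, 1 - eps), tol = 1e-12)$root
  }
}
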