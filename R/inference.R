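#' Posterior of the average treatment effect from paired differences
#'
#' Fits the paired Bayesian model to the per-participant condition
#' differences d_i: `d_i ~ N(delta, sigma_d^2)` with `delta ~ N(mean, sd^2)`
#' from the fitting prior.  In known-variance mode the posterior is the
#' conjugate normal in closed form.  In unknown-variance mode (the default)
#' `sigma_d^2` is marginalized by deterministic Gauss-Legendre quadrature on
#' the log-variance axis under the variance prior, with `delta` integrated in
#' closed form conditional on each variance node; the posterior is the
#' resulting mixture of normals.  No Monte-Carlo sampler is involved, so
#' results are exactly reproducible.
#'
#' `fit_ate()` takes a [trial_dataset()]; `ate_posterior()` is the
#' lower-level worker on a difference vector.
#'
#' @param dataset A [trial_dataset()].
#' @param d Numeric vector of per-participant differences (see
#'   [paired_differences()]).
#' @param prior A [fitting_prior()]; default is the neutral N(0, 0.40^2) with
#'   a Jeffreys variance prior.
#' @param cri_level Credible level for the equal-tailed interval (default
#'   0.95).
#'
#' @return An object of class `ate_posterior` with fields `mean`, `sd`,
#'   `cri_low`, `cri_high`, `cri_level`, `prob_positive` (posterior mass
#'   above zero), `n`, and `mode`.
#' @examples
#' ds <- draw_prior_predictive(generative_priors(), n = 25, seed = 3)
#' fit_ate(ds)
#'
#' # conjugate closed form with known variance:
#' fit <- ate_posterior(c(0.1, 0.3, 0.5, 0.7),
#'                      fitting_prior(sigma_d = 0.4))
#' fit$mean  # (n/sigma^2 dbar) / (1/s0^2 + n/sigma^2) = 0.32
#' @export
fit_ate <- function(dataset, prior = fitting_prior(), cri_level = 0.95) {
  ate_posterior(paired_differences(dataset), prior, cri_level)
}

#' @rdname fit_ate
#' @export
ate_posterior <- function(d, prior = fitting_prior(), cri_level = 0.95) {
  if (!inherits(prior, "fitting_prior"))
    stop("`prior` must be a fitting_prior object", call. = FALSE)
  if (!is.numeric(cri_level) || cri_level <= 0 || cri_level >= 1)
    stop("`cri_level` must be in (0, 1)", call. = FALSE)
  n_min <- if (prior$mode == "known_variance") 2L else 3L
  if (length(d) < n_min)
    stop("invalid design: at least ", n_min, " participants are required",
         call. = FALSE)
  mix <- posterior_mixture(d, prior)
  alpha <- (1 - cri_level) / 2
  q <- mixture_quantile(mix, c(alpha, 1 - alpha))
  structure(list(
    mean = mixture_mean(mix),
    sd = mixture_sd(mix),
    cri_low = q[1],
    cri_high = q[2],
    cri_level = cri_level,
    prob_positive = 1 - mixture_cdf(mix, 0),
    n = mix$st$n,
    mode = prior$mode,
    prior = prior,
    mixture = mix
  ), class = "ate_posterior")
}

#' @export
print.ate_posterior <- function(x, digits = 3, ...) {
  cat(sprintf("Average treatment effect posterior (%s, n = %d)\n",
              gsub("_", " ", x$mode), x$n))
  cat(sprintf("  mean %s, SD %s, %d%% CrI [%s, %s]\n",
              format(x$mean, digits = digits),
              format(x$sd, digits = digits),
              round(100 * x$cri_level),
              format(x$cri_low, digits = digits),
              format(x$cri_high, digits = digits)))
  cat(sprintf("  P(delta > 0) = %s\n",
              format(x$prob_positive, digits = digits)))
  invisible(x)
}

#' Posterior density of the average treatment effect
#'
#' Evaluates the (mixture) posterior density of `delta` from a fitted
#' [ate_posterior]; used, for example, by the Savage-Dickey Bayes-factor
#' cross-check.
#'
#' @param fit An `ate_posterior` object.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of density values.
#' @export
ate_posterior_density <- function(fit, x) {
  stopifnot(inherits(fit, "ate_posterior"))
  mixture_density(fit$mixture, x)
}

#' Qualitative magnitude of a standardized effect
#'
#' Classifies the absolute value of a standardized effect into
#' trivial/small/medium/large bands.  The default cut-points 0.15, 0.45 and
#' 0.75 follow quantile-based thresholds for the distribution of effects in
#' strength-and-conditioning interventions; they are fully configurable.
#' A value exactly at a cut-point is assigned to the larger category.
#'
#' @param effect Numeric vector of standardized effects.
#' @param thresholds Strictly increasing positive cut-points separating
#'   trivial/small, small/medium and medium/large.
#' @return Character vector of labels.
#' @examples
#' classify_magnitude(c(0, -0.2, 0.45, 1.1))
#' @export
classify_magnitude <- function(effect, thresholds = c(0.15, 0.45, 0.75)) {
  if (length(thresholds) != 3L || any(!is.finite(thresholds)) ||
      any(diff(thresholds) <= 0) || thresholds[1] < 0)
    stop("`thresholds` must be three strictly increasing non-negative values",
         call. = FALSE)
  labels <- c("trivial", "small", "medium", "large")
  # findInterval counts thresholds <= |effect|: ties go to the larger band
  labels[findInterval(abs(effect), thresholds) + 1L]
}
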