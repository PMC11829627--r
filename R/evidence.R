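#' Log marginal likelihood of the paired differences under each hypothesis
#'
#' Computes the log marginal likelihood of the differences `d` under the null
#' hypothesis H0 (`delta = 0`, variance marginalized) or the alternative H1
#' (`delta` additionally integrated against its normal fitting prior), using
#' the same deterministic quadrature as [ate_posterior()].  In known-variance
#' mode both marginals are available in closed form.  Under the (improper)
#' Jeffreys variance prior the two values share an arbitrary common constant,
#' which cancels in the Bayes factor.
#'
#' @param d Numeric vector of per-participant differences.
#' @param hypothesis `"alternative"` or `"null"`.
#' @param prior A [fitting_prior()].
#' @return A single number: the log marginal likelihood.
#' @seealso [bayes_factor()]
#' @examples
#' d <- c(0.2, 0.5, 0.1, 0.6, 0.3)
#' marginal_likelihood(d, "alternative") - marginal_likelihood(d, "null")
#' @export
marginal_likelihood <- function(d, hypothesis = c("alternative", "null"),
                                prior = fitting_prior()) {
  hypothesis <- match.arg(hypothesis)
  n_min <- if (prior$mode == "known_variance") 2L else 3L
  if (length(d) < n_min)
    stop("invalid design: at least ", n_min, " participants are required",
         call. = FALSE)
  st <- diff_stats(d)
  if (prior$mode == "known_variance") {
    u <- 2 * log(prior$sigma_d)
    return(log_cond_ml(u, st, prior, hypothesis))
  }
  if (st$S <= 0)
    stop(paste("all differences are identical: the change-score variance is",
               "degenerate; supply a known-variance fitting prior",
               "(sigma_d) instead"), call. = FALSE)
  variance_grid(st, prior, hypothesis)$log_ml
}

#' Bayes factor for the average treatment effect
#'
#' Compares H1 (`delta` drawn from the fitting prior) against H0
#' (`delta = 0`) via the ratio of marginal likelihoods,
#' `bf10 = ML(H1) / ML(H0)`.  Values above 1 support the existence of a
#' condition difference; values below 1 support the null of equal
#' improvement.  Under equal prior model probabilities the posterior
#' probability of H1 is `bf10 / (1 + bf10)`.  All computation is in log
#' space, and the returned `bf10` is clamped away from 0 and infinity.
#'
#' @inheritParams marginal_likelihood
#' @return An object of class `evidence_result` with fields `bf10`,
#'   `log_bf10`, `posterior_model_prob_h1`, and `label` (see
#'   [label_evidence()]).
#' @examples
#' ds <- draw_prior_predictive(generative_priors(), n = 25, seed = 9)
#' bayes_factor(paired_differences(ds))
#' @export
bayes_factor <- function(d, prior = fitting_prior()) {
  log_bf <- marginal_likelihood(d, "alternative", prior) -
    marginal_likelihood(d, "null", prior)
  log_bf <- min(max(log_bf, -690), 690)  # keep exp() strictly in (0, Inf)
  bf10 <- exp(log_bf)
  structure(list(bf10 = bf10,
                 log_bf10 = log_bf,
                 posterior_model_prob_h1 = stats::plogis(log_bf),
                 label = label_evidence(bf10)),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, digits = 3, ...) {
  cat(sprintf("BF10 = %s (%s)\n", format(x$bf10, digits = digits), x$label))
  cat(sprintf("  posterior probability of H1 (equal prior odds) = %s\n",
              format(x$posterior_model_prob_h1, digits = digits)))
  invisible(x)
}

#' Savage-Dickey density-ratio Bayes factor
#'
#' Independent cross-check of [bayes_factor()]: for this nested pair (H0 is
#' H1 with `delta = 0`, and the variance prior is shared) the Bayes factor
#' equals the ratio of prior to posterior density of `delta` at zero.
#'
#' @inheritParams marginal_likelihood
#' @return A single number, the Savage-Dickey estimate of `bf10`.
#' @examples
#' d <- c(0.2, 0.5, 0.1, 0.6, 0.3)
#' savage_dickey_bf(d)
#' bayes_factor(d)$bf10
#' @export
savage_dickey_bf <- function(d, prior = fitting_prior()) {
  fit <- ate_posterior(d, prior)
  stats::dnorm(0, prior$mean, prior$sd) / ate_posterior_density(fit, 0)
}

#' Qualitative evidence label for a Bayes factor
#'
#' Maps `bf10` to the conventional gradation of evidence strength with
#' cut-points 1, 3, 10, 30 and 100 (and their reciprocals on the null side):
#' anecdotal, moderate, strong, very strong, extreme.  A Bayes factor of
#' exactly 1 carries no evidence either way; a value exactly at a cut-point
#' is assigned to the stronger category.
#'
#' @param bf10 Positive numeric vector of Bayes factors (H1 over H0).
#' @param cutpoints Strictly increasing cut-points on the null side, in
#'   `(0, 1)`, from strongest to weakest; defaults to
#'   `c(1/100, 1/30, 1/10, 1/3)`.
#' @return Character vector of labels such as `"Moderate evidence for H0"`.
#' @examples
#' label_evidence(c(0.39, 0.16, 1, 4.2, 150))
#' @export
label_evidence <- function(bf10, cutpoints = c(1 / 100, 1 / 30, 1 / 10,
                                               1 / 3)) {
  if (any(!is.finite(bf10)) || any(bf10 <= 0))
    stop("`bf10` must be positive", call. = FALSE)
  if (any(diff(cutpoints) <= 0) || any(cutpoints <= 0) || any(cutpoints >= 1))
    stop("`cutpoints` must be strictly increasing and inside (0, 1)",
         call. = FALSE)
  strength <- c("Extreme", "Very strong", "Strong", "Moderate", "Anecdotal")
  vapply(bf10, function(b) {
    if (b == 1) return("No evidence")
    side <- if (b < 1) "H0" else "H1"
    r <- min(b, 1 / b)
    # left-open intervals: a ratio exactly at a cut-point takes the
    # stronger label
    k <- findInterval(r, cutpoints, left.open = TRUE) + 1L
    paste(strength[k], "evidence for", side)
  }, character(1))
}
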