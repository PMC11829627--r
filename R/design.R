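#' Credible-interval precision across candidate sample sizes
#'
#' Estimates the precision a trial design can expect for the average
#' treatment effect: for each candidate sample size, repeatedly simulates
#' prior-predictive datasets from the generative priors, fits the paired
#' model with the fitting prior, and summarizes the length of the
#' equal-tailed credible interval across simulations.
#'
#' @param priors A [generative_priors()] object (the informative simulation
#'   priors).
#' @param fit_prior A [fitting_prior()] used for every fit (default: the
#'   neutral N(0, 0.40^2)).
#' @param n_list Candidate sample sizes (each at least 3).
#' @param n_sims Simulated datasets per sample size (at least 2; default
#'   500).
#' @param seed Integer seed; required so that the whole curve is exactly
#'   reproducible.
#' @param cri_level Credible level (default 0.95).
#' @param interval Coverage of the across-simulation summary interval
#'   (default 0.95, i.e. the 2.5 and 97.5 percentiles).
#' @param ... Passed to [draw_prior_predictive()] (e.g. `measurement`,
#'   `response_per_condition`).
#'
#' @details Individual fit failures are skipped and counted; if more than 5%
#'   of iterations fail at any sample size the run aborts.
#'
#' @return A data frame of class `precision_curve` with columns `n`,
#'   `mean_cri_length`, `cri_length_lo`, `cri_length_hi`, `n_sims`,
#'   `n_failed`.  The per-iteration lengths are kept in the `lengths`
#'   attribute (a list indexed by sample size).
#' @examples
#' \donttest{
#' precision_curve(n_list = c(20, 25, 30), n_sims = 100, seed = 1)
#' }
#' @export
precision_curve <- function(priors = generative_priors(),
                            fit_prior = fitting_prior(),
                            n_list = c(20, 25, 30),
                            n_sims = 500,
                            seed,
                            cri_level = 0.95,
                            interval = 0.95,
                            ...) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` is required", call. = FALSE)
  if (n_sims < 2) stop("`n_sims` must be at least 2", call. = FALSE)
  if (any(n_list < 3)) stop("every sample size must be at least 3",
                            call. = FALSE)
  set.seed(as.integer(seed))
  probs <- c((1 - interval) / 2, 1 - (1 - interval) / 2)
  lengths <- list()
  rows <- lapply(n_list, function(n) {
    len <- rep(NA_real_, n_sims)
    for (i in seq_len(n_sims)) {
      ds <- draw_prior_predictive(priors, n, ...)
      len[i] <- tryCatch({
        fit <- fit_ate(ds, fit_prior, cri_level = cri_level)
        fit$cri_high - fit$cri_low
      }, error = function(e) NA_real_)
    }
    n_failed <- sum(is.na(len))
    if (n_failed > 0.05 * n_sims)
      stop(sprintf("%d of %d fits failed at n = %d", n_failed, n_sims, n),
           call. = FALSE)
    if (n_failed > 0)
      message(sprintf("n = %d: skipped %d failed fit(s)", n, n_failed))
    len <- len[!is.na(len)]
    lengths[[as.character(n)]] <<- len
    qs <- stats::quantile(len, probs, names = FALSE)
    data.frame(n = n, mean_cri_length = mean(len),
               cri_length_lo = qs[1], cri_length_hi = qs[2],
               n_sims = n_sims, n_failed = n_failed)
  })
  out <- do.call(rbind, rows)
  structure(out, lengths = lengths, seed = as.integer(seed),
            cri_level = cri_level,
            class = c("precision_curve", "data.frame"))
}

#' Simulation-based calibration of Bayes factors
#'
#' Checks whether, at each candidate sample size, the design would allocate
#' posterior model probability to the correct hypothesis.  Equal prior model
#' probabilities are assumed: in half of the iterations the average
#' treatment effect is set to zero (H0 true), in the other half it is drawn
#' from the prior selected by `effect_source` (H1 true); every other
#' generative component is always drawn.  Each simulated dataset is fitted
#' with the neutral fitting prior and scored by the posterior model
#' probability `bf10 / (1 + bf10)`.
#'
#' Calibration is summarized by (a) the average posterior model probability
#' over all iterations, which should match the expected 50% when the two
#' hypotheses are equally represented, and (b) the average share of
#' posterior model probability allocated to the true hypothesis on each
#' side.
#'
#' @inheritParams precision_curve
#' @param neutral_prior The [fitting_prior()] used for every fit and Bayes
#'   factor (default N(0, 0.40^2)).
#' @param n_sims Iterations per sample size; must be even (half per
#'   hypothesis).
#' @param effect_source Where the H1-true average treatment effects come
#'   from.  `"neutral"` (default) draws them from the same neutral prior
#'   used for fitting — the self-consistent calibration under which the
#'   average posterior model probability is exactly 50% in expectation.
#'   `"generative"` draws them from the informative ATE prior in `priors`
#'   instead, calibrating against the effects the design actually expects.
#'
#' @return A data frame of class `sbc_result` with columns `n`,
#'   `mean_pmp_pct`, `pmp_lo_pct`, `pmp_hi_pct` (across-simulation summary
#'   interval), `pct_to_h1_when_h1_true`, `pct_to_h0_when_h0_true`,
#'   `n_sims`, `n_failed`.  Per-iteration posterior model probabilities and
#'   truth indicators are kept in the `iterations` attribute.
#' @examples
#' \donttest{
#' sbc_bayes_factors(n_list = 25, n_sims = 100, seed = 2)
#' }
#' @export
sbc_bayes_factors <- function(priors = generative_priors(),
                              neutral_prior = fitting_prior(),
                              n_list = c(20, 25, 30),
                              n_sims = 500,
                              seed,
                              interval = 0.95,
                              effect_source = c("neutral", "generative"),
                              ...) {
  effect_source <- match.arg(effect_source)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` is required", call. = FALSE)
  if (n_sims < 2 || n_sims %% 2 != 0)
    stop("`n_sims` must be an even number >= 2 (half per hypothesis)",
         call. = FALSE)
  set.seed(as.integer(seed))
  h1_priors <- if (effect_source == "neutral") {
    pl <- unclass(priors)
    pl$ate_mean <- neutral_prior$mean
    pl$ate_sd <- neutral_prior$sd
    do.call(generative_priors, pl)
  } else priors
  iterations <- list()
  rows <- lapply(n_list, function(n) {
    h1_true <- rep(c(TRUE, FALSE), length.out = n_sims)
    pmp <- rep(NA_real_, n_sims)
    for (i in seq_len(n_sims)) {
      ds <- draw_prior_predictive(if (h1_true[i]) h1_priors else priors, n,
                                  null_effect = !h1_true[i], ...)
      pmp[i] <- tryCatch(
        bayes_factor(paired_differences(ds),
                     neutral_prior)$posterior_model_prob_h1,
        error = function(e) NA_real_)
    }
    n_failed <- sum(is.na(pmp))
    if (n_failed > 0.05 * n_sims)
      stop(sprintf("%d of %d fits failed at n = %d", n_failed, n_sims, n),
           call. = FALSE)
    if (n_failed > 0)
      message(sprintf("n = %d: skipped %d failed fit(s)", n, n_failed))
    keep <- !is.na(pmp)
    iterations[[as.character(n)]] <<- data.frame(pmp = pmp[keep],
                                                 h1_true = h1_true[keep])
    summarize_sbc(pmp[keep], h1_true[keep], n = n, n_sims = n_sims,
                  n_failed = n_failed, interval = interval)
  })
  out <- do.call(rbind, rows)
  structure(out, iterations = iterations, seed = as.integer(seed),
            class = c("sbc_result", "data.frame"))
}

#' Summarize calibration iterations
#'
#' Reduces per-iteration posterior model probabilities and truth indicators
#' to the calibration metrics reported by [sbc_bayes_factors()].  Exposed so
#' that the reduction can be tested in isolation (e.g. a degenerate evidence
#' stream with `pmp = 0.5` everywhere gives exactly 50% across the board).
#'
#' @param pmp Numeric vector of posterior model probabilities of H1.
#' @param h1_true Logical vector: was H1 the generating hypothesis?
#' @param n,n_sims,n_failed Bookkeeping columns for the output row.
#' @param interval Coverage of the across-iteration percentile interval.
#' @return A one-row data frame (percentages in 0-100).
#' @export
summarize_sbc <- function(pmp, h1_true, n = NA_integer_,
                          n_sims = length(pmp), n_failed = 0L,
                          interval = 0.95) {
  stopifnot(length(pmp) == length(h1_true), all(pmp >= 0 & pmp <= 1))
  probs <- c((1 - interval) / 2, 1 - (1 - interval) / 2)
  qs <- stats::quantile(pmp, probs, names = FALSE)
  data.frame(
    n = n,
    mean_pmp_pct = 100 * mean(pmp),
    pmp_lo_pct = 100 * qs[1],
    pmp_hi_pct = 100 * qs[2],
    pct_to_h1_when_h1_true = 100 * mean(pmp[h1_true]),
    pct_to_h0_when_h0_true = 100 * mean(1 - pmp[!h1_true]),
    n_sims = n_sims,
    n_failed = n_failed
  )
}

#' Combined design table: precision and Bayes-factor calibration
#'
#' Runs [precision_curve()] and [sbc_bayes_factors()] with the same settings
#' and merges the results into one table per sample size, mirroring the
#' layout used when reporting Bayesian sample-size determination: mean CrI
#' length with its across-simulation interval, average posterior model
#' probability with its interval, and the percentage of posterior allocated
#' to each hypothesis when it is true.
#'
#' @inheritParams precision_curve
#' @inheritParams sbc_bayes_factors
#' @return A data frame of class `calibration_table`.
#' @examples
#' \donttest{
#' calibration_table(n_list = c(20, 25), n_sims = 100, seed = 5)
#' }
#' @export
calibration_table <- function(priors = generative_priors(),
                              fit_prior = fitting_prior(),
                              neutral_prior = fitting_prior(),
                              n_list = c(20, 25, 30),
                              n_sims = 500,
                              seed,
                              ...) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` is required", call. = FALSE)
  prec <- precision_curve(priors, fit_prior, n_list, n_sims, seed = seed, ...)
  sbc <- sbc_bayes_factors(priors, neutral_prior, n_list, n_sims,
                           seed = as.integer(seed) + 1L, ...)
  out <- merge(as.data.frame(prec)[, c("n", "mean_cri_length",
                                       "cri_length_lo", "cri_length_hi")],
               as.data.frame(sbc)[, c("n", "mean_pmp_pct", "pmp_lo_pct",
                                      "pmp_hi_pct", "pct_to_h1_when_h1_true",
                                      "pct_to_h0_when_h0_true", "n_sims")],
               by = "n")
  structure(out, seed = as.integer(seed),
            class = c("calibration_table", "data.frame"))
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("Bayesian sample-size determination:",
      "CrI precision and Bayes-factor calibration\n")
  df <- data.frame(
    n = x$n,
    `CrI length [interval]` = sprintf("%.2f [%.2f-%.2f]", x$mean_cri_length,
                                      x$cri_length_lo, x$cri_length_hi),
    `Avg PMP % [interval]` = sprintf("%.1f [%.1f-%.1f]", x$mean_pmp_pct,
                                      x$pmp_lo_pct, x$pmp_hi_pct),
    `% to H1 | H1` = sprintf("%.0f%%", x$pct_to_h1_when_h1_true),
    `% to H0 | H0` = sprintf("%.0f%%", x$pct_to_h0_when_h0_true),
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}
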