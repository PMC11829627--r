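#' Analyse one or more trial outcomes end to end
#'
#' For each outcome dataset, fits the paired Bayesian model, computes the
#' Bayes factor with its qualitative label, and collects pre/post
#' descriptives, producing one report row per outcome in the style of a
#' published group-difference table: estimate with credible interval, the
#' posterior probability of a positive value (favouring the full-ROM
#' condition), and the Bayes factor.
#'
#' For raw-unit outcomes the standardized-scale fitting prior is rescaled by
#' the pooled baseline SD (prior SD 0.40 becomes `0.40 * SD_pooled`), so that
#' estimates are reported in measurement units while the prior keeps its
#' standardized meaning; the rescaling is logged per outcome.  Outcomes are
#' fitted independently.
#'
#' @param inputs A named list of [trial_dataset()] objects and/or CSV file
#'   paths (see [read_trial_csv()]); names become outcome names (file paths
#'   without names use the file base name).
#' @param fit_prior Standardized-scale [fitting_prior()] (default
#'   N(0, 0.40^2)).
#' @param cri_level Credible level (default 0.95).
#' @param drop_incomplete Drop participants missing one condition (with a
#'   warning) when reading CSV inputs; complete-case handling.
#' @param scale Scale assumed when reading CSV inputs.
#' @param quiet Suppress per-outcome log messages.
#'
#' @return A data frame of class `trial_report` with one row per outcome:
#'   `outcome`, `n`, `estimate`, `cri_low`, `cri_high`, `prob_positive`,
#'   `bf10`, `evidence`, `sd_pooled`, `unit`, and per-condition pre/post
#'   descriptive columns (for raw data).  Values are taken directly from the
#'   underlying [ate_posterior] and [bayes_factor()] results without
#'   recomputation.
#' @examples
#' ds <- draw_raw_cohort(cohort_presets()$elbow_flexor_55, n = 25, seed = 11)
#' run_trial_analysis(list(elbow_flexor_55 = ds))
#' @export
run_trial_analysis <- function(inputs, fit_prior = fitting_prior(),
                               cri_level = 0.95, drop_incomplete = TRUE,
                               scale = "raw", quiet = FALSE) {
  if (inherits(inputs, "trial_dataset") || is.character(inputs))
    inputs <- as.list(inputs)
  if (!length(inputs)) stop("no inputs supplied", call. = FALSE)
  nm <- names(inputs)
  if (is.null(nm)) nm <- rep("", length(inputs))
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    x <- inputs[[i]]
    if (is.character(x)) {
      if (nm[i] == "") nm[i] <- sub("\\.csv$", "", basename(x))
      x <- read_trial_csv(x, scale = scale,
                          drop_incomplete = drop_incomplete)
    }
    if (!inherits(x, "trial_dataset"))
      stop("input `", nm[i], "` is not a trial_dataset or CSV path",
           call. = FALSE)
    if (nm[i] == "") nm[i] <- paste0("outcome_", i)
    rows[[i]] <- analyze_outcome(nm[i], x, fit_prior, cri_level, quiet)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fit_prior = fit_prior, cri_level = cri_level,
            class = c("trial_report", "data.frame"))
}

analyze_outcome <- function(name, dataset, fit_prior, cri_level, quiet) {
  raw <- attr(dataset, "scale") == "raw"
  sd_pooled <- NA_real_
  prior_k <- fit_prior
  if (raw) {
    sd_pooled <- pooled_baseline_sd(dataset)
    prior_k <- rescale_fitting_prior(fit_prior, sd_pooled)
    if (!quiet)
      message(sprintf(
        "%s: pooled baseline SD = %.4g; ATE prior rescaled to N(%.4g, %.4g^2)",
        name, sd_pooled, prior_k$mean, prior_k$sd))
  }
  d <- paired_differences(dataset)
  fit <- ate_posterior(d, prior_k, cri_level = cri_level)
  ev <- bayes_factor(d, prior_k)
  desc <- condition_descriptives(dataset)
  cbind(
    data.frame(outcome = name, n = fit$n,
               estimate = fit$mean, cri_low = fit$cri_low,
               cri_high = fit$cri_high,
               prob_positive = fit$prob_positive,
               bf10 = ev$bf10, evidence = ev$label,
               sd_pooled = sd_pooled,
               unit = attr(dataset, "unit_label")),
    desc
  )
}

condition_descriptives <- function(dataset) {
  out <- data.frame(row.names = 1L)
  labels <- c(`0` = "prom", `1` = "from")
  for (cond in c(0L, 1L)) {
    sub <- dataset[dataset$condition == cond, , drop = FALSE]
    for (col in c("pre", "post")) {
      v <- if (is.null(sub[[col]])) NA_real_ else sub[[col]]
      out[[paste0(col, "_mean_", labels[as.character(cond)])]] <- mean(v)
      out[[paste0(col, "_sd_", labels[as.character(cond)])]] <- stats::sd(v)
    }
  }
  out
}

#' @export
print.trial_report <- function(x, digits = 3, ...) {
  cat("Estimated group differences (positive values favour full ROM)\n")
  lvl <- round(100 * attr(x, "cri_level"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-20s %s [%s to %s] %s, p = %.3f, BF10 = %.2f (%s)\n",
                x$outcome[i],
                format(x$estimate[i], digits = digits),
                format(x$cri_low[i], digits = digits),
                format(x$cri_high[i], digits = digits),
                x$unit[i], x$prob_positive[i], x$bf10[i], x$evidence[i]))
  }
  cat(sprintf("  (%d%% equal-tailed credible intervals; p is the posterior probability of a positive difference)\n",
              lvl))
  invisible(x)
}

#' Write a trial report to CSV and/or JSON
#'
#' @param report A `trial_report` from [run_trial_analysis()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_trial_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(report), json_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}

#' Generate a suite of synthetic cohort fixture files
#'
#' Writes one CSV per cohort preset (by default the six bundled outcomes:
#' four muscle-thickness sites and two 10 RM tests) with `n` participants
#' and two conditions each, generated by [draw_raw_cohort()].  Files are
#' named `synthetic_<outcome>.csv` to make clear that they contain no real
#' participant data.
#'
#' @param dir Output directory (created if needed).
#' @param presets Named list of [cohort_preset()] objects.
#' @param priors A [generative_priors()] object.
#' @param n Participants per cohort (default 25).
#' @param seed Integer seed; required (two runs with the same seed produce
#'   byte-identical files).
#' @param force Overwrite into a non-empty directory.
#' @return Character vector of the files written, invisibly.
#' @examples
#' \donttest{
#' make_fixture_suite(tempfile("fixtures"), seed = 1)
#' }
#' @export
make_fixture_suite <- function(dir, presets = cohort_presets(),
                               priors = generative_priors(), n = 25,
                               seed, force = FALSE) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` is required", call. = FALSE)
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("output directory is not empty; use force = TRUE to overwrite",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  paths <- character(0)
  for (preset in presets) {
    ds <- draw_raw_cohort(preset, priors, n)
    path <- file.path(dir, paste0("synthetic_", preset$outcome_name, ".csv"))
    write_trial_csv(ds, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
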