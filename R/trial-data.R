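#' Construct and validate a within-participant trial dataset
#'
#' A trial dataset holds one change score per participant per condition for a
#' two-condition within-participant design.  Condition is coded 0 for the
#' reference condition (partial range of motion, pROM) and 1 for the
#' intervention condition (full range of motion, fROM), so positive treatment
#' effects favour the intervention.  Raw-scale datasets additionally carry
#' `pre` and `post` columns in measurement units.
#'
#' @param data A data frame with columns `participant_id`, `condition`,
#'   `change`, and optionally `pre` and `post`.  `condition` may be coded
#'   `0`/`1` or `"pROM"`/`"fROM"`.
#' @param scale Either `"standardized"` (change scores in baseline-SD units)
#'   or `"raw"`.
#' @param unit_label Unit of the change scores, e.g. `"SD"`, `"mm"`, `"kg"`.
#'
#' @details Validation requires exactly two records per participant, one per
#'   condition, and no missing change values.  The original row order is not
#'   meaningful; all downstream computations order by `participant_id`.
#'
#' @return A `trial_dataset`: a data frame with attributes `scale` and
#'   `unit_label`.
#' @seealso [draw_prior_predictive()], [read_trial_csv()],
#'   [paired_differences()]
#' @examples
#' trial_dataset(data.frame(
#'   participant_id = rep(c("P1", "P2"), each = 2),
#'   condition = rep(0:1, 2),
#'   change = c(0.5, 0.8, 0.1, 0.4)
#' ))
#' @export
trial_dataset <- function(data, scale = c("standardized", "raw"),
                          unit_label = if (scale == "raw") "unit" else "SD") {
  scale <- match.arg(scale)
  data <- as.data.frame(data)
  required <- c("participant_id", "condition", "change")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data$condition <- recode_condition(data$condition)
  data$participant_id <- as.character(data$participant_id)
  validate_trial_dataset(data)
  structure(data, scale = scale, unit_label = unit_label,
            class = c("trial_dataset", "data.frame"))
}

recode_condition <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- tolower(trimws(as.character(x)))
    map <- c(prom = 0L, from = 1L, "0" = 0L, "1" = 1L)
    if (!all(x %in% names(map)))
      stop("condition must be coded 0/1 or pROM/fROM", call. = FALSE)
    unname(map[x])
  } else {
    x <- as.integer(x)
    if (anyNA(x) || !all(x %in% c(0L, 1L)))
      stop("condition must be coded 0/1 or pROM/fROM", call. = FALSE)
    x
  }
}

validate_trial_dataset <- function(data) {
  if (anyNA(data$change) || !all(is.finite(data$change)))
    stop("change scores must be present and finite for every record",
         call. = FALSE)
  tab <- table(data$participant_id, data$condition)
  if (ncol(tab) != 2L || !all(tab == 1L))
    stop("each participant must have exactly two records, one per condition",
         call. = FALSE)
  invisible(data)
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- length(unique(x$participant_id))
  cat(sprintf("Within-participant trial dataset: %d participants, %s scale (%s)\n",
              n, attr(x, "scale"), attr(x, "unit_label")))
  rlz <- attr(x, "realized")
  if (!is.null(rlz))
    cat(sprintf("  realized typical improvement = %.4g, realized ATE = %.4g\n",
                rlz$theta, rlz$delta))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Per-participant condition differences in change scores
#'
#' Reduces a trial dataset to the vector of within-participant differences
#' d_i = change(condition 1) - change(condition 0).  Because the design is
#' complete (both conditions observed in every participant), participant-level
#' effects shared across limbs cancel in these differences, and the paired
#' model on d is likelihood-equivalent to the full mixed model for the
#' average treatment effect.
#'
#' @param dataset A [trial_dataset()].
#' @return A named numeric vector of differences, ordered by
#'   `participant_id`.
#' @examples
#' ds <- draw_prior_predictive(generative_priors(), n = 8, seed = 1)
#' paired_differences(ds)
#' @export
paired_differences <- function(dataset) {
  validate_trial_dataset(dataset)
  o <- order(dataset$participant_id, dataset$condition)
  x <- dataset[o, ]
  c1 <- x$change[x$condition == 1L]
  c0 <- x$change[x$condition == 0L]
  d <- c1 - c0
  names(d) <- unique(x$participant_id[order(x$participant_id)])
  d
}

#' Pooled baseline standard deviation
#'
#' The SD used to move between raw and standardized scales: the square root
#' of the mean of the per-condition baseline (`pre`) variances.
#'
#' @param dataset A raw-scale [trial_dataset()] with a `pre` column.
#' @return A single positive number.
#' @export
pooled_baseline_sd <- function(dataset) {
  if (is.null(dataset$pre))
    stop("dataset has no `pre` column; pooled baseline SD is undefined",
         call. = FALSE)
  v <- tapply(dataset$pre, dataset$condition, stats::var)
  sqrt(mean(v))
}

#' Standardize a raw-unit trial dataset
#'
#' Divides raw change scores by the pooled baseline SD (square root of the
#' mean per-condition baseline variance), flipping the dataset to the
#' standardized scale on which the priors are set.  The pooling formula and
#' the SD used are recorded in the `standardization` attribute.
#'
#' @param dataset A raw-scale [trial_dataset()] with `pre` values.
#' @param if_standardized What to do when `dataset` is already standardized:
#'   `"error"` (default) or `"identity"` (return unchanged).
#' @return A standardized `trial_dataset`.
#' @examples
#' ds <- draw_raw_cohort(cohort_preset("mt", 39.6, 8.6), n = 12, seed = 1)
#' std <- standardize_changes(ds)
#' attr(std, "standardization")$sd_pooled
#' @export
standardize_changes <- function(dataset,
                                if_standardized = c("error", "identity")) {
  if_standardized <- match.arg(if_standardized)
  if (attr(dataset, "scale") == "standardized") {
    if (if_standardized == "identity") return(dataset)
    stop("dataset is already standardized", call. = FALSE)
  }
  sd_pooled <- pooled_baseline_sd(dataset)
  if (!is.finite(sd_pooled) || sd_pooled <= 0)
    stop("pooled baseline SD is zero; cannot standardize a degenerate scale",
         call. = FALSE)
  out <- dataset
  out$change <- dataset$change / sd_pooled
  attr(out, "scale") <- "standardized"
  attr(out, "unit_label") <- "SD"
  attr(out, "standardization") <- list(
    sd_pooled = sd_pooled,
    formula = "sqrt(mean(per-condition baseline variances))"
  )
  out
}

#' Read and write trial datasets as CSV
#'
#' CSV files have a header and columns `participant_id, condition, pre, post,
#' change` (`pre`/`post` optional for standardized data; `change` is computed
#' as `post - pre` when absent).  Condition may be coded `0`/`1` or
#' `pROM`/`fROM`.
#'
#' @param path File path.
#' @param scale,unit_label Scale and unit of the stored change scores (see
#'   [trial_dataset()]).
#' @param drop_incomplete If `TRUE`, participants missing one condition are
#'   dropped with a warning (complete-case handling); if `FALSE` (default)
#'   such files fail validation.
#' @return `read_trial_csv()` returns a [trial_dataset()];
#'   `write_trial_csv()` returns `path` invisibly.
#' @examples
#' ds <- draw_prior_predictive(generative_priors(), n = 6, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_trial_csv(ds, f)
#' identical(paired_differences(read_trial_csv(f, scale = "standardized")),
#'           paired_differences(ds))
#' @export
read_trial_csv <- function(path, scale = c("raw", "standardized"),
                           unit_label = NULL, drop_incomplete = FALSE) {
  scale <- match.arg(scale)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("participant_id", "condition") %in% names(df)))
    stop(path, ": columns participant_id and condition are required",
         call. = FALSE)
  df$condition <- recode_condition(df$condition)
  if (is.null(df$change)) {
    if (is.null(df$pre) || is.null(df$post))
      stop(path, ": need either a change column or pre and post columns",
           call. = FALSE)
    df$change <- df$post - df$pre
  }
  if (drop_incomplete) {
    tab <- table(df$participant_id)
    bad <- names(tab)[tab != 2L]
    bad <- union(bad, names(which(tapply(df$condition, df$participant_id,
                                         function(x) length(unique(x))) != 2L)))
    if (length(bad)) {
      warning("dropping participant(s) without both conditions: ",
              paste(bad, collapse = ", "), call. = FALSE)
      df <- df[!(df$participant_id %in% bad), , drop = FALSE]
    }
  }
  if (is.null(unit_label))
    unit_label <- if (scale == "raw") "unit" else "SD"
  trial_dataset(df, scale = scale, unit_label = unit_label)
}

#' @rdname read_trial_csv
#' @param dataset A [trial_dataset()] to write.
#' @param condition_labels If `TRUE` (default), condition is written as
#'   `pROM`/`fROM`; otherwise as `0`/`1`.
#' @export
write_trial_csv <- function(dataset, path, condition_labels = TRUE) {
  cols <- intersect(c("participant_id", "condition", "pre", "post", "change"),
                    names(dataset))
  out <- as.data.frame(dataset)[, cols, drop = FALSE]
  if (condition_labels)
    out$condition <- ifelse(out$condition == 1L, "fROM", "pROM")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
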