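# Performance measures with the indeterminate-exclusion convention:
# indeterminate calls are counted separately and excluded from every
# confusion-matrix denominator.

normalize_prediction <- function(p) {
  if (is.numeric(p)) {
    return(dplyr::case_when(p > 0 ~ "sensitizer", p < 0 ~ "non-sensitizer",
                            TRUE ~ "indeterminate"))
  }
  p <- as.character(p)
  ok <- p %in% c("sensitizer", "non-sensitizer", "indeterminate")
  if (!all(ok)) {
    abort(paste0("Unrecognized prediction label(s): ",
                 paste(unique(p[!ok]), collapse = ", ")),
          class = "skinqsar_value_error")
  }
  p
}

normalize_truth <- function(y) {
  if (is.numeric(y)) return(ifelse(y > 0, "sensitizer", "non-sensitizer"))
  y <- as.character(y)
  ok <- y %in% c("sensitizer", "non-sensitizer")
  if (!all(ok)) {
    abort("Truth labels must be binary (sensitizer / non-sensitizer)",
          class = "skinqsar_value_error")
  }
  y
}

#' Tally predictions against truth
#'
#' Builds the confusion counts. Indeterminate predictions go to
#' `n_indeterminate` and are excluded from `tp`/`fp`/`tn`/`fn` — an
#' indeterminate call classifies nothing, so it cannot be right or wrong.
#'
#' @param predictions Labels (`sensitizer` / `non-sensitizer` /
#'   `indeterminate`) or numeric scores (+/0/-).
#' @param truth Binary labels or +/-1 (no indeterminate).
#' @return Object of class `confusion_tally` with fields `tp`, `fp`, `tn`,
#'   `fn`, `n_indeterminate`.
#' @export
tally_predictions <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) == 0) {
    abort("predictions and truth must be equal-length and non-empty",
          class = "skinqsar_length_mismatch_error")
  }
  p <- normalize_prediction(predictions)
  y <- normalize_truth(truth)
  det <- p != "indeterminate"
  structure(
    list(
      tp = sum(det & p == "sensitizer" & y == "sensitizer"),
      fp = sum(det & p == "sensitizer" & y == "non-sensitizer"),
      tn = sum(det & p == "non-sensitizer" & y == "non-sensitizer"),
      fn = sum(det & p == "non-sensitizer" & y == "sensitizer"),
      n_indeterminate = sum(!det),
      n = length(p)
    ),
    class = "confusion_tally"
  )
}

#' @export
print.confusion_tally <- function(x, ...) {
  cat("<confusion_tally> TP ", x$tp, ", FP ", x$fp, ", TN ", x$tn,
      ", FN ", x$fn, ", indeterminate ", x$n_indeterminate, "\n", sep = "")
  invisible(x)
}

#' Build a tally directly from counts
#'
#' @param tp,fp,tn,fn,n_indeterminate Non-negative integer counts.
#' @return `confusion_tally`.
#' @export
confusion_tally <- function(tp, fp, tn, fn, n_indeterminate = 0) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn,
              n_indeterminate = n_indeterminate)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         n_indeterminate = n_indeterminate,
         n = tp + fp + tn + fn + n_indeterminate),
    class = "confusion_tally"
  )
}

round_half_up <- function(x, digits = 2) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' Performance measures from a confusion tally
#'
#' Percent-scale measures over the determinate predictions:
#' sensitivity `= TP/(TP+FN)`, specificity `= TN/(TN+FP)`, accuracy
#' `= (TP+TN)/(TP+FN+TN+FP)` and the correct classification rate
#' `CCR = (sensitivity + specificity)/2`. Values are returned unrounded; the
#' print method shows two decimals (half-up).
#'
#' @param t `confusion_tally`.
#' @return Object of class `performance_report` (a one-row tibble with
#'   columns `sensitivity`, `specificity`, `accuracy`, `ccr`,
#'   `n_indeterminate`).
#' @export
compute_metrics <- function(t) {
  stopifnot(inherits(t, "confusion_tally"))
  if (t$tp + t$fn == 0 || t$tn + t$fp == 0) {
    abort("Each class needs at least one determinate prediction",
          class = "skinqsar_degenerate_tally_error")
  }
  sens <- 100 * t$tp / (t$tp + t$fn)
  spec <- 100 * t$tn / (t$tn + t$fp)
  acc <- 100 * (t$tp + t$tn) / (t$tp + t$fn + t$tn + t$fp)
  structure(
    tibble(
      sensitivity = sens, specificity = spec, accuracy = acc,
      ccr = (sens + spec) / 2, n_indeterminate = t$n_indeterminate
    ),
    class = c("performance_report", class(tibble()))
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>\n")
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%  CCR %.2f%%\n",
              round_half_up(x$sensitivity), round_half_up(x$specificity),
              round_half_up(x$accuracy), round_half_up(x$ccr)))
  cat("  indeterminate:", x$n_indeterminate, "\n")
  invisible(x)
}

#' Evaluate workflow results against known labels
#'
#' Convenience wrapper: tallies the `label` column of [run_workflow()]
#' output against the molecules' potency-derived truth and computes the
#' performance report.
#'
#' @param results [run_workflow()] output.
#' @param mols Labeled molecule tibble matching `results$id`.
#' @return `performance_report`.
#' @export
evaluate_workflow <- function(results, mols) {
  truth <- ifelse(is_sensitizer(mols$potency[match(results$id, mols$id)]),
                  "sensitizer", "non-sensitizer")
  ok <- !is.na(results$label)
  compute_metrics(tally_predictions(results$label[ok], truth[ok]))
}

#' Curation arithmetic for an externally collated set
#'
#' Applies the standard exclusion steps used when assembling a challenge
#' set: molecules already present in the parent set, molecules failing
#' format conversion, and molecules failing structure optimization are
#' removed from the collated total.
#'
#' @param n_collated Molecules collated from the literature.
#' @param n_in_parent Overlap with the parent set.
#' @param n_failed_conversion Failures at format conversion.
#' @param n_failed_optimization Failures at 3D optimization.
#' @return One-row tibble with the exclusion counts and `n_retained`.
#' @export
curation_summary <- function(n_collated, n_in_parent = 0,
                             n_failed_conversion = 0,
                             n_failed_optimization = 0) {
  retained <- n_collated - n_in_parent - n_failed_conversion -
    n_failed_optimization
  stopifnot(retained >= 0)
  tibble(
    n_collated = n_collated, n_in_parent = n_in_parent,
    n_failed_conversion = n_failed_conversion,
    n_failed_optimization = n_failed_optimization,
    n_retained = retained
  )
}
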