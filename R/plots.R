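# ggplot2 visualizations for result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_col geom_point
#'   geom_vline geom_jitter labs theme_minimal scale_fill_manual
#' @export
ggplot2::autoplot

LABEL_FILLS <- c(sensitizer = "#c0392b", `non-sensitizer` = "#2980b9",
                 indeterminate = "#7f8c8d")

#' Plot consensus results
#'
#' Histogram of consensus scores colored by the assigned label; the zero
#' line marks the indeterminate boundary.
#'
#' @param object [run_workflow()] output.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot consensus_results
#' @export
autoplot.consensus_results <- function(object, ...) {
  df <- object |> filter(!is.na(.data$score))
  ggplot(df, aes(x = .data$score, fill = .data$label)) +
    geom_histogram(binwidth = 0.2, boundary = 0, color = "white") +
    geom_vline(xintercept = 0, linetype = "dashed") +
    scale_fill_manual(values = LABEL_FILLS) +
    labs(x = "consensus score", y = "molecules", fill = NULL,
         title = "Weighted consensus scores") +
    theme_minimal()
}

#' Plot a Y-randomization record
#'
#' Real-label accuracy against the permuted-label accuracies; a wide gap
#' indicates the model is not a chance correlation.
#'
#' @param object `y_randomization`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot y_randomization
#' @export
autoplot.y_randomization <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$labels, y = .data$accuracy,
                 color = .data$labels)) +
    geom_jitter(width = 0.05, height = 0, size = 2, show.legend = FALSE) +
    labs(x = NULL, y = "accuracy",
         title = paste0("Y-randomization, variant ", object$code)) +
    theme_minimal()
}

#' Plot a performance report
#'
#' Bar chart of sensitivity, specificity, accuracy and CCR.
#'
#' @param object `performance_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot performance_report
#' @export
autoplot.performance_report <- function(object, ...) {
  df <- tibble(
    measure = factor(c("sensitivity", "specificity", "accuracy", "CCR"),
                     levels = c("sensitivity", "specificity", "accuracy", "CCR")),
    value = c(object$sensitivity, object$specificity, object$accuracy,
              object$ccr)
  )
  ggplot(df, aes(x = .data$measure, y = .data$value)) +
    geom_col(fill = "#2c3e50") +
    labs(x = NULL, y = "percent", title = "Prediction performance") +
    theme_minimal()
}
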