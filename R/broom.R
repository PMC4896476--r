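# broom-style accessors for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained QSAR variant
#'
#' One row per feature with an importance measure where the underlying
#' classifier provides one (mean Gini decrease for the tree ensemble,
#' variable importance for the decision tree, absolute coefficient for the
#' logistic and linear max-margin fits; `NA` for the perceptron).
#'
#' @param x `qsar_variant`.
#' @param ... Unused.
#' @return Tibble `term`, `importance`.
#' @method tidy qsar_variant
#' @export
tidy.qsar_variant <- function(x, ...) {
  imp <- switch(x$classifier,
    RF = {
      v <- randomForest::importance(x$fit)[, 1]
      tibble(term = names(v), importance = unname(v))
    },
    J48 = {
      v <- x$fit$variable.importance
      if (is.null(v)) tibble(term = character(0), importance = numeric(0))
      else tibble(term = names(v), importance = unname(v))
    },
    SL = {
      cf <- stats::coef(x$fit)
      cf <- cf[setdiff(names(cf), "(Intercept)")]
      tibble(term = names(cf), importance = abs(unname(cf)))
    },
    SMO = {
      w <- drop(t(x$fit$coefs) %*% x$fit$SV)
      tibble(term = names(w), importance = abs(unname(w)))
    },
    tibble(term = x$features, importance = NA_real_)
  )
  full_join(tibble(term = x$features), imp, by = "term") |>
    arrange(desc(.data$importance))
}

#' Glance at a trained QSAR variant
#'
#' @param x `qsar_variant`.
#' @param ... Unused.
#' @return One-row tibble: `code`, `classifier`, `split_method`, `set_id`,
#'   `n_train`, `n_features`, `cv_accuracy`.
#' @method glance qsar_variant
#' @export
glance.qsar_variant <- function(x, ...) {
  tibble(
    code = format_variant_code(x$code),
    classifier = x$classifier,
    split_method = x$code$split_method,
    set_id = x$code$set_id,
    n_train = x$n_train,
    n_features = length(x$features),
    cv_accuracy = x$cv_accuracy
  )
}

#' Tidy a Y-randomization record
#'
#' @param x `y_randomization`.
#' @param ... Unused.
#' @return Tibble `run`, `labels` (`real`/`permuted`), `accuracy`.
#' @method tidy y_randomization
#' @export
tidy.y_randomization <- function(x, ...) {
  bind_rows(
    tibble(run = 0L, labels = "real", accuracy = x$real_accuracy),
    tibble(run = seq_along(x$randomized_accuracies), labels = "permuted",
           accuracy = x$randomized_accuracies)
  )
}

#' Glance at a Y-randomization record
#'
#' @param x `y_randomization`.
#' @param ... Unused.
#' @return One-row tibble with the real accuracy, the permuted mean/max and
#'   the real-minus-max margin.
#' @method glance y_randomization
#' @export
glance.y_randomization <- function(x, ...) {
  tibble(
    code = x$code,
    real_accuracy = x$real_accuracy,
    permuted_mean = mean(x$randomized_accuracies),
    permuted_max = max(x$randomized_accuracies),
    margin = x$real_accuracy - max(x$randomized_accuracies),
    runs = x$runs
  )
}

#' Tidy a confusion tally
#'
#' @param x `confusion_tally`.
#' @param ... Unused.
#' @return Tibble `cell`, `n`.
#' @method tidy confusion_tally
#' @export
tidy.confusion_tally <- function(x, ...) {
  tibble(
    cell = c("tp", "fp", "tn", "fn", "indeterminate"),
    n = c(x$tp, x$fp, x$tn, x$fn, x$n_indeterminate)
  )
}

#' Glance at a workflow bundle
#'
#' @param x `pw_bundle`.
#' @param ... Unused.
#' @return One-row tibble summarizing the bundle.
#' @method glance pw_bundle
#' @export
glance.pw_bundle <- function(x, ...) {
  tibble(
    workflow = x$workflow,
    m2 = unname(x$codes["m2"]), m3 = unname(x$codes["m3"]),
    m4 = unname(x$codes["m4"]),
    scheme = attr(x$scheme, "scheme"),
    n_reference = nrow(x$reference),
    n_alerts = nrow(x$library)
  )
}
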