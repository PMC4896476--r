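# QSAR variant grid: per-model dataset assembly, D/S/C train-test splits,
# five classifier families addressed by alphanumeric variant codes
# (e.g. "2C2RF" = model-2, cross-validation split, descriptor set-2, random
# forest), diverse-subset selection and Y-randomization.

# importFrom also forces these namespaces to load with the package, so their
# predict() S3 methods are registered for models restored from disk.
#' @importFrom randomForest randomForest
#' @importFrom e1071 svm
#' @importFrom rpart rpart
#' @importFrom nnet nnet
NULL

CLASSIFIER_TOKENS <- c("J48", "MLP", "RF", "SL", "SMO")
DEFAULT_SEED <- 20160607

#' Parse a QSAR variant code
#'
#' Codes read `<model 1-4><split D|S|C><descriptor set 1-5><classifier>`,
#' with classifier one of `J48`, `MLP`, `RF`, `SL`, `SMO`.
#'
#' @param code Code string such as `"2C2RF"`.
#' @return Object of class `variant_code` with fields `model_id`,
#'   `split_method`, `set_id`, `classifier`.
#' @examples
#' parse_variant_code("1D4RF")
#' @export
parse_variant_code <- function(code) {
  if (inherits(code, "variant_code")) return(code)
  m <- regmatches(code, regexec("^([1-4])([DSC])([1-5])(J48|MLP|RF|SL|SMO)$", code))[[1]]
  if (length(m) == 0) {
    abort(paste0("Not a valid variant code: ", code),
          class = "skinqsar_variant_code_error")
  }
  structure(
    list(model_id = as.integer(m[2]), split_method = m[3],
         set_id = as.integer(m[4]), classifier = m[5]),
    class = "variant_code"
  )
}

#' Format a variant code back to its string form
#'
#' @param x `variant_code` object.
#' @return The code string, e.g. `"2C2RF"`.
#' @export
format_variant_code <- function(x) {
  paste0(x$model_id, x$split_method, x$set_id, x$classifier)
}

#' @export
print.variant_code <- function(x, ...) {
  cat("<variant_code ", format_variant_code(x), "> model-", x$model_id,
      ", split ", x$split_method, ", descriptor set-", x$set_id,
      ", classifier ", x$classifier, "\n", sep = "")
  invisible(x)
}

#' Assemble the training dataset for one QSAR model
#'
#' The four potency-stratified models draw from the labeled parent pool:
#' * model-1: extreme (`X`) and strong (`St`) sensitizers plus the
#'   `diverse_nonsens_k` least-average-similarity non-sensitizers (all
#'   non-sensitizers would bias the model toward the majority class);
#' * model-2: `X`, `St` and unknown-potency sensitizers `S`, all `N`;
#' * model-3: moderate (`M`) sensitizers, all `N`;
#' * model-4: weak (`W`) sensitizers, all `N`.
#'
#' Sensitizer-side records get `label = +1`, non-sensitizers `-1`.
#'
#' @param eo Labeled molecule tibble (the energy-optimized parent pool).
#' @param model_id Integer 1..4.
#' @param diverse_nonsens_k Non-sensitizer count for model-1.
#' @param fp Optional precomputed fingerprint matrix of `eo` (speeds up the
#'   model-1 diversity pick).
#' @return Molecule tibble with an added `label` column (+1/-1).
#' @export
assemble_model_dataset <- function(eo, model_id, diverse_nonsens_k = 49,
                                   fp = NULL) {
  if (!model_id %in% 1:4) {
    abort("model_id must be 1..4", class = "skinqsar_value_error")
  }
  sens_classes <- switch(model_id, c("X", "St"), c("X", "St", "S"), "M", "W")
  sens <- eo |> filter(.data$potency %in% sens_classes)
  nonsens <- eo |> filter(.data$potency == "N")
  missing <- setdiff(sens_classes, unique(sens$potency))
  if (length(missing) > 0) {
    abort(paste0("Required potency class(es) empty: ",
                 paste(missing, collapse = ", ")),
          class = "skinqsar_value_error")
  }
  if (nrow(nonsens) == 0) {
    abort("No non-sensitizers in the pool", class = "skinqsar_value_error")
  }
  if (model_id == 1) {
    if (diverse_nonsens_k > nrow(nonsens)) {
      abort("diverse_nonsens_k exceeds the non-sensitizer count",
            class = "skinqsar_value_error")
    }
    sub_fp <- if (!is.null(fp)) fp[nonsens$id, , drop = FALSE] else NULL
    nonsens <- select_diverse(nonsens, diverse_nonsens_k,
                              mode = "least-average-similarity", fp = sub_fp)
  }
  bind_rows(sens, nonsens) |>
    mutate(label = ifelse(is_sensitizer(.data$potency), 1L, -1L))
}

#' Split a dataset for training and testing
#'
#' Three strategies:
#' * `D` (direct): shuffle, then an 80/20 train/test cut;
#' * `S` (separation): sensitizers and non-sensitizers are pre-segregated and
#'   each split 80/20, guaranteeing proportional class representation;
#' * `C` (cross-validation): an `n_folds`-fold partition; every molecule is
#'   in exactly one test fold.
#'
#' All strategies are reproducible under a fixed seed.
#'
#' @param mols Molecule tibble with a `label` or `potency` column.
#' @param method `"D"`, `"S"` or `"C"`.
#' @param seed Integer RNG seed.
#' @param n_folds Fold count for `C`.
#' @param train_frac Training fraction for `D`/`S`.
#' @return For `D`/`S` a tibble `id`, `subset` (`train`/`test`); for `C` a
#'   tibble `id`, `fold`.
#' @export
split_dataset <- function(mols, method = c("D", "S", "C"), seed = DEFAULT_SEED,
                          n_folds = 10, train_frac = 0.8) {
  method <- match.arg(method)
  lab <- dataset_labels(mols)
  if (length(unique(lab)) < 2) {
    abort("Both classes must be present to split",
          class = "skinqsar_degenerate_input_error")
  }
  n <- nrow(mols)
  withr::with_seed(seed, {
    switch(method,
      D = {
        idx <- sample.int(n)
        n_train <- round(train_frac * n)
        tibble(id = mols$id[idx],
               subset = rep(c("train", "test"), c(n_train, n - n_train)))
      },
      S = {
        purrr::map_dfr(split(mols$id, lab), function(ids) {
          ids <- sample(ids)
          k <- round(train_frac * length(ids))
          tibble(id = ids,
                 subset = rep(c("train", "test"), c(k, length(ids) - k)))
        })
      },
      C = {
        if (n < n_folds) {
          abort("Fewer molecules than folds", class = "skinqsar_value_error")
        }
        idx <- sample.int(n)
        tibble(id = mols$id[idx], fold = rep_len(seq_len(n_folds), n)) |>
          arrange(match(.data$id, mols$id))
      }
    )
  })
}

dataset_labels <- function(mols) {
  if ("label" %in% names(mols)) {
    binary_labels(mols$label)
  } else {
    ifelse(is_sensitizer(mols$potency), 1, -1)
  }
}

# ---- classifier families ----------------------------------------------------

fit_classifier <- function(classifier, x, y01, seed = DEFAULT_SEED) {
  # x: numeric matrix; y01: factor with levels "-1","1"
  if (!classifier %in% CLASSIFIER_TOKENS) {
    abort(paste0("Unknown classifier: ", classifier),
          class = "skinqsar_unknown_classifier_error")
  }
  df <- as.data.frame(x)
  df$.y <- y01
  withr::with_seed(seed, switch(classifier,
    RF = randomForest::randomForest(x = x, y = y01, ntree = 100),
    J48 = rpart::rpart(.y ~ ., data = df, method = "class"),
    MLP = {
      p <- ncol(x)
      size <- min(max(2, floor((p + 2) / 2)), 20)
      nnet::nnet(.y ~ ., data = df, size = size, decay = 1e-4, maxit = 200,
                 trace = FALSE, MaxNWts = 50000)
    },
    SMO = {
      keep <- apply(x, 2, stats::sd) > 0
      e1071::svm(x = x[, keep, drop = FALSE], y = y01, kernel = "linear",
                 scale = TRUE)
    },
    SL = suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    )
  ))
}

predict_classifier <- function(fit, classifier, x) {
  df <- as.data.frame(x)
  pred <- switch(classifier,
    RF = as.character(predict(fit, x)),
    J48 = as.character(predict(fit, df, type = "class")),
    MLP = as.character(predict(fit, df, type = "class")),
    SMO = {
      keep <- colnames(fit$SV)
      as.character(predict(fit, x[, keep, drop = FALSE]))
    },
    SL = ifelse(suppressWarnings(predict(fit, df, type = "response")) > 0.5,
                "1", "-1")
  )
  as.integer(pred)
}

#' Train a QSAR variant
#'
#' Fits the classifier family named by the variant code on the molecules and
#' features supplied, using the code's split method. For `D`/`S` the model is
#' fitted on the training portion and the held-out portion is kept for
#' evaluation; for `C` the model is fitted on the full dataset and fold-wise
#' cross-validated accuracy is recorded. All families use their standard
#' defaults except the tree ensemble, which grows 100 trees.
#'
#' @param code Variant code string or `variant_code`.
#' @param mols Labeled molecule tibble (`label` or `potency` column).
#' @param features Feature tibble with `id` column covering all molecules.
#' @param feature_set Optional [feature_set()] restricting the feature
#'   columns; defaults to all.
#' @param seed Integer RNG seed (splits and stochastic fits).
#' @param n_folds Fold count when the code's split method is `C`.
#' @return Object of class `qsar_variant`; [predict()] on it maps molecules
#'   to `+1` (sensitizer) / `-1` (non-sensitizer).
#' @export
train_variant <- function(code, mols, features, feature_set = NULL,
                          seed = DEFAULT_SEED, n_folds = 10) {
  code <- parse_variant_code(code)
  feats <- if (is.null(feature_set)) setdiff(names(features), "id")
           else feature_set$features
  x_all <- as_feature_matrix(features)[mols$id, feats, drop = FALSE]
  y_all <- dataset_labels(mols)
  y_fac <- factor(y_all, levels = c(-1, 1), labels = c("-1", "1"))

  split <- split_dataset(mols, code$split_method, seed = seed, n_folds = n_folds)

  if (code$split_method == "C") {
    cv_pred <- rep(NA_integer_, nrow(mols))
    for (f in sort(unique(split$fold))) {
      test_ids <- split$id[split$fold == f]
      tr <- !(mols$id %in% test_ids)
      fit_f <- fit_classifier(code$classifier, x_all[tr, , drop = FALSE],
                              y_fac[tr], seed = seed + f)
      cv_pred[!tr] <- predict_classifier(fit_f, code$classifier,
                                         x_all[!tr, , drop = FALSE])
    }
    cv_accuracy <- mean(cv_pred == y_all)
    fit <- fit_classifier(code$classifier, x_all, y_fac, seed = seed)
    train_ids <- mols$id
    test_ids <- character(0)
  } else {
    train_ids <- split$id[split$subset == "train"]
    test_ids <- split$id[split$subset == "test"]
    tr <- mols$id %in% train_ids
    fit <- fit_classifier(code$classifier, x_all[tr, , drop = FALSE],
                          y_fac[tr], seed = seed)
    cv_accuracy <- NA_real_
  }

  structure(
    list(code = code, classifier = code$classifier, features = feats,
         fit = fit, train_ids = train_ids, test_ids = test_ids,
         split = split, cv_accuracy = cv_accuracy, seed = seed,
         n_train = length(train_ids)),
    class = "qsar_variant"
  )
}

#' Predict with a trained QSAR variant
#'
#' @param object `qsar_variant`.
#' @param features Feature tibble with `id` column (must contain the
#'   variant's features).
#' @param ... Unused.
#' @return Named integer vector of votes in `{-1, +1}`.
#' @export
predict.qsar_variant <- function(object, features, ...) {
  x <- as_feature_matrix(features)[, object$features, drop = FALSE]
  setNames(predict_classifier(object$fit, object$classifier, x), rownames(x))
}

#' @export
print.qsar_variant <- function(x, ...) {
  cat("<qsar_variant ", format_variant_code(x$code), "> ",
      length(x$features), " features, ", x$n_train, " training molecules",
      if (!is.na(x$cv_accuracy))
        paste0(", CV accuracy ", sprintf("%.3f", x$cv_accuracy)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Held-out accuracy of a variant
#'
#' For `D`/`S` variants, accuracy on the internal test set; for `C`
#' variants, the recorded cross-validated accuracy.
#'
#' @param variant `qsar_variant`.
#' @param mols Labeled molecule tibble the variant was trained from.
#' @param features Feature tibble.
#' @return Accuracy in `[0, 1]`.
#' @export
variant_accuracy <- function(variant, mols, features) {
  if (variant$code$split_method == "C") return(variant$cv_accuracy)
  test <- mols |> filter(.data$id %in% variant$test_ids)
  votes <- predict(variant, features |> filter(.data$id %in% test$id))
  mean(votes[test$id] == dataset_labels(test))
}

#' Select a structurally diverse subset
#'
#' Two modes:
#' * `least-average-similarity`: the `k` molecules with the smallest mean
#'   pairwise Tanimoto coefficient to the rest of the pool (self excluded);
#' * `stratified-representative`: per-potency-class greedy max-min diversity
#'   picks at the class quotas given in `quotas` (e.g.
#'   `c(X = 10, St = 10, S = 10, M = 10, W = 10, N = 50)`).
#'
#' Ties break lexicographically by molecule id, so the selection is
#' deterministic and invariant to input order.
#'
#' @param pool Molecule tibble.
#' @param k Subset size (`least-average-similarity` mode).
#' @param mode Selection mode.
#' @param quotas Named integer vector of per-class counts
#'   (`stratified-representative` mode).
#' @param fp Optional precomputed fingerprint matrix of `pool`.
#' @return Molecule tibble subset.
#' @export
select_diverse <- function(pool, k = nrow(pool),
                           mode = c("least-average-similarity",
                                    "stratified-representative"),
                           quotas = NULL, fp = NULL) {
  mode <- match.arg(mode)
  fp <- fp %||% fingerprint_matrix(pool)
  sim <- tanimoto_matrix(fp)

  if (mode == "least-average-similarity") {
    if (k > nrow(pool)) {
      abort("k exceeds pool size", class = "skinqsar_value_error")
    }
    if (nrow(pool) == 1) return(pool)
    avg <- (rowSums(sim) - diag(sim)) / (nrow(pool) - 1)
    ord <- order(avg, pool$id)
    pool[sort(ord[seq_len(k)]), , drop = FALSE]
  } else {
    if (is.null(quotas)) {
      abort("stratified-representative mode needs class quotas",
            class = "skinqsar_value_error")
    }
    picked <- character(0)
    for (cls in names(quotas)) {
      in_cls <- which(pool$potency == cls)
      q <- quotas[[cls]]
      if (q > length(in_cls)) {
        abort(paste0("Quota for class ", cls, " (", q,
                     ") exceeds class size (", length(in_cls), ")"),
              class = "skinqsar_value_error")
      }
      # seed with the least-average-similarity member, then max-min
      sub_sim <- sim[in_cls, in_cls, drop = FALSE]
      avg <- if (length(in_cls) == 1) 0 else
        (rowSums(sub_sim) - diag(sub_sim)) / (length(in_cls) - 1)
      chosen <- in_cls[order(avg, pool$id[in_cls])[1]]
      while (length(chosen) < q) {
        rest <- setdiff(in_cls, chosen)
        # distance to the chosen set = 1 - max similarity to it
        min_dist <- 1 - apply(sim[rest, chosen, drop = FALSE], 1, max)
        nxt <- rest[order(-min_dist, pool$id[rest])[1]]
        chosen <- c(chosen, nxt)
      }
      picked <- c(picked, pool$id[chosen])
    }
    pool |> filter(.data$id %in% picked)
  }
}

#' Y-randomization of a QSAR variant
#'
#' Trains once on the true labels and `runs` more times on random label
#' permutations, evaluating each model identically (held-out accuracy for
#' `D`/`S` codes, cross-validated accuracy for `C`). A real-data model that
#' clearly outperforms every permuted run shows the fit is not a chance
#' correlation.
#'
#' @inheritParams train_variant
#' @param runs Number of permutation runs (default 10).
#' @return Object of class `y_randomization` with fields `real_accuracy` and
#'   `randomized_accuracies`.
#' @export
y_randomize <- function(code, mols, features, feature_set = NULL, runs = 10,
                        seed = DEFAULT_SEED, n_folds = 10) {
  code <- parse_variant_code(code)
  real <- train_variant(code, mols, features, feature_set, seed = seed,
                        n_folds = n_folds)
  real_acc <- variant_accuracy(real, mols, features)
  rand_acc <- vapply(seq_len(runs), function(r) {
    perm <- withr::with_seed(seed + r, sample(dataset_labels(mols)))
    mols_r <- mols |> mutate(label = perm)
    v <- train_variant(code, mols_r, features, feature_set, seed = seed,
                       n_folds = n_folds)
    variant_accuracy(v, mols_r, features)
  }, numeric(1))
  structure(
    list(code = format_variant_code(code), real_accuracy = real_acc,
         randomized_accuracies = rand_acc, runs = runs),
    class = "y_randomization"
  )
}

#' @export
print.y_randomization <- function(x, ...) {
  cat("<y_randomization ", x$code, ">\n",
      "  real accuracy:      ", sprintf("%.3f", x$real_accuracy), "\n",
      "  permuted (", x$runs, " runs): mean ",
      sprintf("%.3f", mean(x$randomized_accuracies)), ", max ",
      sprintf("%.3f", max(x$randomized_accuracies)), "\n", sep = "")
  invisible(x)
}
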