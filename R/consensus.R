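# Knowledge-based consensus: direction-specific weights per component, a
# signed weighted-sum score, and the sensitizer / non-sensitizer /
# indeterminate sign rule; plus machine-learning meta-integration of the
# component votes and the full prediction-workflow driver.

COMPONENTS <- c("m2", "m3", "m4", "similarity", "substructure")

kb_weight_rows <- function(name, m2, m3, m4, sim, sub) {
  tibble(
    component = c(rep("m2", 2), rep("m3", 2), rep("m4", 2),
                  rep("similarity", 4), rep("substructure", 2)),
    direction = c("S", "N", "S", "N", "S", "N",
                  "S", "N", "NS", "NoMatch", "Present", "Absent"),
    weight = c(m2, m3, m4, sim, sub)
  ) |>
    structure(scheme = name, class = c("weight_scheme", class(tibble())))
}

# The four built-in knowledge-based weight assignments. S/N (and
# Present/Absent, NS/NoMatch) columns are the weight applied when the
# component predicts in that direction; an absent sub-structure is
# down-weighted (0.5) because absence is weaker evidence than presence.
BUILTIN_SCHEMES <- list(
  "KB-a" = list(m2 = c(1, 1),   m3 = c(0.4, 0.4), m4 = c(0.3, 0.3),
                sim = c(1, 1, 0, 0), sub = c(1, 0.5)),
  "KB-b" = list(m2 = c(1, 0.8), m3 = c(0.8, 0.4), m4 = c(0.3, 0.4),
                sim = c(1, 1, 0, 0), sub = c(1, 0.5)),
  "KB-c" = list(m2 = c(1, 0.8), m3 = c(0.6, 0.4), m4 = c(0.3, 0.4),
                sim = c(1, 1, 0, 0), sub = c(1, 0.5)),
  "KB-d" = list(m2 = c(1, 0.8), m3 = c(0.4, 0.3), m4 = c(0.3, 0.3),
                sim = c(1, 1, 0, 0), sub = c(1, 0.5))
)

#' A knowledge-based weight scheme
#'
#' Returns one of the four built-in schemes (`KB-a` .. `KB-d`) as a tibble of
#' direction-specific component weights, or validates a custom scheme passed
#' as a tibble with columns `component`, `direction`, `weight`. Every
#' (component, direction) pair must be present and all weights must be
#' non-negative.
#'
#' @param name Scheme name or a custom weights tibble.
#' @return `weight_scheme` tibble.
#' @export
weight_scheme <- function(name = "KB-b") {
  if (inherits(name, "weight_scheme")) return(name)
  if (is.data.frame(name)) {
    ws <- as_tibble(name)
    need <- kb_weight_rows("custom", c(0, 0), c(0, 0), c(0, 0),
                           c(0, 0, 0, 0), c(0, 0))[, c("component", "direction")]
    have <- paste(ws$component, ws$direction)
    missing <- setdiff(paste(need$component, need$direction), have)
    if (length(missing) > 0) {
      abort(paste0("Weight scheme missing pair(s): ",
                   paste(missing, collapse = "; ")),
            class = "skinqsar_unknown_scheme_error")
    }
    if (any(ws$weight < 0)) {
      abort("Weights must be non-negative", class = "skinqsar_value_error")
    }
    return(structure(ws, scheme = attr(name, "scheme") %||% "custom",
                     class = c("weight_scheme", class(tibble()))))
  }
  if (!name %in% names(BUILTIN_SCHEMES)) {
    abort(paste0("Unknown weight scheme: ", name,
                 ". Built-ins: ", paste(names(BUILTIN_SCHEMES), collapse = ", ")),
          class = "skinqsar_unknown_scheme_error")
  }
  s <- BUILTIN_SCHEMES[[name]]
  kb_weight_rows(name, s$m2, s$m3, s$m4, s$sim, s$sub)
}

#' Look up one direction-specific weight
#'
#' @param scheme Scheme name or `weight_scheme` tibble.
#' @param component One of `m2`, `m3`, `m4`, `similarity`, `substructure`.
#' @param direction `S`/`N` for QSAR components, `S`/`N`/`NS`/`NoMatch` for
#'   similarity, `Present`/`Absent` for substructure.
#' @return The tabulated weight.
#' @export
lookup_weight <- function(scheme, component, direction) {
  ws <- weight_scheme(scheme)
  hit <- ws$weight[ws$component == component & ws$direction == direction]
  if (length(hit) == 0) {
    abort(paste0("No weight for (", component, ", ", direction, ")"),
          class = "skinqsar_key_error")
  }
  hit[1]
}

component_direction <- function(component, value, sim_direction = NULL) {
  if (component == "similarity") return(sim_direction)
  if (component == "substructure") {
    return(if (value > 0) "Present" else "Absent")
  }
  if (value > 0) "S" else "N"
}

#' Consensus score from five component votes
#'
#' Computes the weighted sum
#' `score = m2*w_m2 + m3*w_m3 + m4*w_m4 + s_similarity*w_similarity +
#' s_substr*w_substr`, each weight looked up by the direction the component
#' predicts. A positive score classifies the molecule as sensitizer, negative
#' as non-sensitizer, and exactly zero (after rounding to 10 decimals; exact
#' for the tenth-valued built-in weights) as indeterminate.
#'
#' @param components Tibble with columns `component` (all five of `m2`, `m3`,
#'   `m4`, `similarity`, `substructure`), `value` (-1/0/+1; 0 only for
#'   similarity) and, for the similarity row, `direction` (`S`, `N`, `NS` or
#'   `NoMatch`).
#' @param scheme Scheme name or `weight_scheme`.
#' @return One-row tibble `score`, `label`.
#' @export
consensus_score <- function(components, scheme = "KB-b") {
  ws <- weight_scheme(scheme)
  components <- as_tibble(components)
  if (!setequal(components$component, COMPONENTS) ||
      nrow(components) != length(COMPONENTS)) {
    abort("Exactly one vote per component (m2, m3, m4, similarity, substructure) is required",
          class = "skinqsar_incomplete_components_error")
  }
  bad0 <- components$component != "similarity" & components$value == 0
  if (any(bad0)) {
    abort("Only the similarity component may vote 0",
          class = "skinqsar_value_error")
  }
  if (!"direction" %in% names(components)) components$direction <- NA_character_
  score <- sum(vapply(seq_len(nrow(components)), function(i) {
    comp <- components$component[i]
    val <- components$value[i]
    dir <- component_direction(comp, val, components$direction[i])
    val * lookup_weight(ws, comp, dir)
  }, numeric(1)))
  score <- round(score, 10)
  tibble(score = score, label = score_label(score))
}

score_label <- function(score) {
  dplyr::case_when(
    score > 0 ~ "sensitizer",
    score < 0 ~ "non-sensitizer",
    TRUE ~ "indeterminate"
  )
}

# ---- workflow bundles -------------------------------------------------------

#' Feature table used by workflow QSAR variants
#'
#' Joins the built-in 2D descriptors (group A) with the binary alert
#' fingerprints (groups B and C) into one feature tibble.
#'
#' @param mols Molecule tibble.
#' @param library Alert tibble.
#' @return Tibble `id` + numeric feature columns.
#' @export
workflow_features <- function(mols, library = default_alert_library()) {
  compute_descriptors(mols) |>
    left_join(alert_fingerprints(mols, library), by = "id")
}

workflow_codes <- function(workflow) {
  switch(workflow,
    "PW-1" = c(m2 = "2C2RF", m3 = "3C2RF", m4 = "4C2RF"),
    "PW-2" = c(m2 = "2C4RF", m3 = "3C2RF", m4 = "4C2RF"),
    abort(paste0("Unknown workflow: ", workflow), class = "skinqsar_value_error")
  )
}

#' Train a full prediction-workflow bundle
#'
#' Assembles the model-2/3/4 datasets from a labeled parent pool, screens
#' group-A descriptors by Welch t-test per model, builds each variant's
#' descriptor set (set-2 or set-4 recipes with CFS/best-first reduction),
#' trains the three QSAR variants named by the workflow (`PW-1` = 2C2RF,
#' 3C2RF, 4C2RF; `PW-2` = 2C4RF, 3C2RF, 4C2RF), and packages them with the
#' reference set, alert library and weight scheme into a reusable bundle.
#'
#' @param eo Labeled molecule tibble (the parent pool; all of `X`/`St`/`S`,
#'   `M`, `W` and `N` must be represented).
#' @param library Alert tibble.
#' @param workflow `"PW-2"` (default, the shipped configuration) or `"PW-1"`.
#' @param scheme Weight scheme for consensus (default `KB-b`).
#' @param seed Integer RNG seed.
#' @param alpha t-test significance level for group-A screening.
#' @param stale_limit Best-first stopping patience.
#' @return Object of class `pw_bundle`.
#' @export
train_workflow <- function(eo, library = default_alert_library(),
                           workflow = c("PW-2", "PW-1"), scheme = "KB-b",
                           seed = DEFAULT_SEED, alpha = 0.05,
                           stale_limit = 5) {
  workflow <- match.arg(workflow)
  codes <- workflow_codes(workflow)
  features <- workflow_features(eo, library)
  desc_names <- setdiff(names(compute_descriptors(eo[1, , drop = FALSE])), "id")
  B <- library$id[!is.na(library$set) & library$set == "B"]
  C <- library$id[!is.na(library$set) & library$set == "C"]

  variants <- purrr::imap(codes, function(code_str, slot) {
    code <- parse_variant_code(code_str)
    dat <- assemble_model_dataset(eo, code$model_id)
    feats_dat <- features |> filter(.data$id %in% dat$id)
    feats_dat <- feats_dat[match(dat$id, feats_dat$id), , drop = FALSE]
    labels <- dat$label
    A <- select_by_ttest(feats_dat[, c("id", desc_names)], labels, alpha)
    if (length(A) == 0) A <- desc_names  # degenerate screen: keep all
    fs <- build_descriptor_set(code$set_id, A, B, C, feats_dat, labels,
                               stale_limit = stale_limit)
    train_variant(code, dat, feats_dat, fs, seed = seed)
  })

  structure(
    list(workflow = workflow, codes = codes, variants = variants,
         reference = eo, reference_fp = fingerprint_matrix(eo),
         library = library, scheme = weight_scheme(scheme), seed = seed),
    class = "pw_bundle"
  )
}

#' @export
print.pw_bundle <- function(x, ...) {
  cat("<pw_bundle ", x$workflow, "> variants: ",
      paste(x$codes, collapse = ", "), "; scheme ",
      attr(x$scheme, "scheme"), "; reference n = ", nrow(x$reference),
      "\n", sep = "")
  invisible(x)
}

#' Save / load a workflow bundle
#'
#' Bundles persist as a single RDS file (classifiers, feature lists, variant
#' codes, reference set, library, scheme and seed all included).
#'
#' @param bundle `pw_bundle`.
#' @param path File path.
#' @return `path` (save) or the restored bundle (load).
#' @export
save_workflow <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_workflow
#' @export
load_workflow <- function(path) {
  readRDS(path)
}

#' Run a prediction workflow over molecules
#'
#' Computes the five component votes per molecule (three QSAR variants,
#' similarity, sub-structure), applies the consensus scheme — or the
#' bundle's meta-model, which never returns indeterminate — and returns one
#' result row per molecule. Component groups named in `ablate` have their
#' contribution zeroed (weight treated as 0). Per-molecule component
#' failures are captured as failure records (`label` `NA`, message in
#' `error`), not batch aborts.
#'
#' @param mols Molecule tibble (labels optional).
#' @param bundle `pw_bundle` from [train_workflow()].
#' @param scheme Optional override of the bundle's scheme, or a `meta_model`.
#' @param ablate Character subset of `c("qsar", "similarity", "substructure")`.
#' @param cutoff Tanimoto cutoff for the similarity component.
#' @return Tibble: `id`, `smiles`, `label`, `score`, the five component
#'   votes, similarity provenance (`sim_direction`, `best_coefficient`,
#'   `nearest_id`, `identical_match`), `mechanisms` (collapsed matched alert
#'   mechanisms) and `error`.
#' @export
run_workflow <- function(mols, bundle, scheme = NULL, ablate = NULL,
                         cutoff = 0.6) {
  stopifnot(inherits(bundle, "pw_bundle"))
  combiner <- scheme %||% bundle$scheme
  if (!is.null(ablate)) {
    bad <- setdiff(ablate, c("qsar", "similarity", "substructure"))
    if (length(bad) > 0) {
      abort(paste0("Unknown ablation group(s): ", paste(bad, collapse = ", ")),
            class = "skinqsar_value_error")
    }
  }
  features <- workflow_features(mols, bundle$library)
  feat_ok <- !apply(is.na(as_feature_matrix(features)), 1, any)

  qsar_votes <- purrr::map(bundle$variants, function(v) {
    votes <- rep(NA_integer_, nrow(mols))
    if (any(feat_ok)) {
      votes[feat_ok] <- predict(v, features[feat_ok, , drop = FALSE])
    }
    votes
  })
  sim <- similarity_scores(mols, bundle$reference, cutoff = cutoff,
                           reference_fp = bundle$reference_fp)
  sub <- substructure_scores(mols, bundle$library)

  use_meta <- inherits(combiner, "meta_model")

  purrr::map_dfr(seq_len(nrow(mols)), function(i) {
    base <- tibble(
      id = mols$id[i], smiles = mols$smiles[i],
      m2 = unname(qsar_votes$m2[i]), m3 = unname(qsar_votes$m3[i]),
      m4 = unname(qsar_votes$m4[i]),
      similarity = sim$score[i], substructure = sub$score[i],
      sim_direction = sim$direction[i],
      best_coefficient = sim$best_coefficient[i],
      nearest_id = if (nrow(sim$neighbors[[i]]) > 0)
        sim$neighbors[[i]]$ref_id[1] else NA_character_,
      identical_match = sim$identical_match[i],
      mechanisms = paste(unique(sub$matches[[i]]$mechanism), collapse = "; ")
    )
    if (!feat_ok[i]) {
      return(base |> mutate(score = NA_real_, label = NA_character_,
                            error = "feature computation failed"))
    }
    comp <- tibble(
      component = COMPONENTS,
      value = c(base$m2, base$m3, base$m4, base$similarity, base$substructure),
      direction = c(NA, NA, NA, base$sim_direction, NA)
    )
    if (!is.null(ablate)) {
      zero <- c(if ("qsar" %in% ablate) c("m2", "m3", "m4"),
                if ("similarity" %in% ablate) "similarity",
                if ("substructure" %in% ablate) "substructure")
    } else {
      zero <- character(0)
    }
    res <- tryCatch({
      if (use_meta) {
        vals <- setNames(comp$value, comp$component)
        vals[zero] <- 0
        lab <- predict(combiner, matrix(vals, nrow = 1,
                                        dimnames = list(NULL, COMPONENTS)))
        tibble(score = as.numeric(lab), label = score_label(as.numeric(lab)))
      } else {
        ws <- weight_scheme(combiner)
        if (length(zero) > 0) ws$weight[ws$component %in% zero] <- 0
        consensus_score(comp, ws)
      }
    }, error = function(e) tibble(score = NA_real_, label = NA_character_,
                                  error = conditionMessage(e)))
    if (!"error" %in% names(res)) res$error <- NA_character_
    bind_cols(base, res)
  }) |>
    relocate("id", "smiles", "label", "score") |>
    structure(class = c("consensus_results", class(tibble())))
}

# ---- meta integration -------------------------------------------------------

#' Meta-integration of component votes
#'
#' Trains a meta-classifier (one-hidden-layer perceptron or linear
#' max-margin) on the raw five-component vote matrix with `n_folds`-fold
#' cross-validated accuracy reporting, then refits on all rows. Its
#' predictions are always sensitizer or non-sensitizer — a trained combiner
#' cannot abstain.
#'
#' @param component_matrix Numeric matrix/tibble, molecules by the five
#'   component votes (values in -1/0/+1).
#' @param labels Binary class vector.
#' @param method `"MLP"` (perceptron) or `"SMO"` (linear max-margin).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer RNG seed.
#' @return Object of class `meta_model` with field `cv_accuracy`.
#' @export
meta_integrate <- function(component_matrix, labels, method = c("MLP", "SMO"),
                           n_folds = 10, seed = DEFAULT_SEED) {
  method <- match.arg(method)
  x <- as_feature_matrix(component_matrix)
  y <- binary_labels(labels)
  if (length(unique(y)) < 2) {
    abort("Meta-integration needs both classes",
          class = "skinqsar_degenerate_input_error")
  }
  if (all(apply(x, 2, stats::sd) == 0)) {
    warn("All component votes constant; falling back to majority-class predictor")
    maj <- if (mean(y) >= 0) 1L else -1L
    return(structure(list(method = "majority", majority = maj,
                          cv_accuracy = max(mean(y == 1), mean(y == -1))),
                     class = "meta_model"))
  }
  y_fac <- factor(y, levels = c(-1, 1), labels = c("-1", "1"))
  folds <- withr::with_seed(seed, rep_len(seq_len(n_folds), nrow(x))[sample.int(nrow(x))])
  cls <- if (method == "MLP") "MLP" else "SMO"
  cv_pred <- rep(NA_integer_, nrow(x))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(y_fac[tr])) < 2) next
    fit_f <- fit_classifier(cls, x[tr, , drop = FALSE], y_fac[tr],
                            seed = seed + f)
    cv_pred[!tr] <- predict_classifier(fit_f, cls, x[!tr, , drop = FALSE])
  }
  fit <- fit_classifier(cls, x, y_fac, seed = seed)
  structure(
    list(method = method, fit = fit, classifier = cls,
         cv_accuracy = mean(cv_pred == y, na.rm = TRUE),
         n_folds = n_folds, seed = seed),
    class = "meta_model"
  )
}

#' Predict with a meta-model
#'
#' @param object `meta_model`.
#' @param newdata Matrix/tibble of component votes.
#' @param ... Unused.
#' @return Integer votes in `{-1, +1}` (never 0).
#' @export
predict.meta_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (object$method == "majority") {
    return(rep(object$majority, nrow(x)))
  }
  predict_classifier(object$fit, object$classifier, x)
}

#' @export
print.meta_model <- function(x, ...) {
  cat("<meta_model ", x$method, "> CV accuracy ",
      sprintf("%.3f", x$cv_accuracy), "\n", sep = "")
  invisible(x)
}
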