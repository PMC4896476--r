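# Descriptor machinery: a compact built-in 2D descriptor provider, Welch
# t-test screening, CFS subset merit, greedy best-first subset search,
# and the five descriptor-set assembly recipes.

#' Built-in 2D molecular descriptors
#'
#' A compact descriptor provider for end-to-end runs: physicochemical
#' properties from OpenBabel (molecular weight, logP, topological polar
#' surface area, molar refractivity, H-bond donor/acceptor counts) plus
#' constitutional counts derived from the canonical SMILES (atoms by element,
#' halogens, aromatic atoms, double/triple bonds, rings, branches).
#' Descriptor computation is pluggable: any tibble with an `id` column and
#' numeric feature columns can stand in wherever this output is accepted.
#'
#' @param mols Molecule tibble.
#' @return Tibble: `id` plus one numeric column per descriptor (all group-A
#'   features).
#' @export
compute_descriptors <- function(mols) {
  conv <- mols_to_sdf(mols)
  props <- ChemmineR::propOB(conv$sdf)
  num_cols <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
  pmat <- matrix(NA_real_, nrow = nrow(mols), ncol = length(num_cols),
                 dimnames = list(mols$id, paste0("desc_", num_cols)))
  pmat[conv$valid, ] <- as.matrix(props[, num_cols])

  smi <- mols$smiles
  count_chr <- function(pattern) stringr::str_count(smi, pattern)
  counts <- tibble(
    desc_n_carbon = count_chr("C(?![ladroun])") + count_chr("c"),
    desc_n_nitrogen = count_chr("N(?![aboe])") + count_chr("n"),
    desc_n_oxygen = count_chr("O(?!s)") + count_chr("o"),
    desc_n_sulfur = count_chr("S(?![icernb])") + count_chr("s"),
    desc_n_halogen = count_chr("Cl") + count_chr("Br") +
      count_chr("F(?![elmr])") + count_chr("I(?![nr])"),
    desc_n_aromatic = count_chr("[cnos]"),
    desc_n_double_bond = count_chr("="),
    desc_n_triple_bond = count_chr("#"),
    desc_n_ring = floor(count_chr("[0-9]") / 2),
    desc_n_branch = count_chr("\\(")
  )
  bind_cols(tibble(id = mols$id), as_tibble(pmat), counts)
}

#' Map features to descriptor groups
#'
#' Group `A` holds statistically screened numeric descriptors, `B` the
#' skin-protein reactive-group fingerprint bits, `C` the literature mechanism
#' fingerprint bits.
#'
#' @param descriptors Output of [compute_descriptors()] (or compatible).
#' @param alert_fp Output of [alert_fingerprints()].
#' @param library Alert tibble with a `set` column assigning `B`/`C`.
#' @return Tibble `feature`, `group`.
#' @export
feature_groups <- function(descriptors, alert_fp, library) {
  bind_rows(
    tibble(feature = setdiff(names(descriptors), "id"), group = "A"),
    tibble(feature = library$id,
           group = dplyr::coalesce(library$set, "C"))
  ) |>
    filter(.data$feature %in% c(setdiff(names(descriptors), "id"),
                                setdiff(names(alert_fp), "id")))
}

as_feature_matrix <- function(data) {
  data <- as.data.frame(data)
  if ("id" %in% names(data)) {
    rownames(data) <- data$id
    data$id <- NULL
  }
  as.matrix(data)
}

binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    labels <- ifelse(labels %in% c("1", "+1", "sensitizer", "S", "pos"), 1, -1)
  }
  labels <- as.numeric(labels)
  stopifnot(all(labels %in% c(-1, 1)))
  labels
}

#' Welch t-test descriptor screening
#'
#' Keeps features whose two-sample unequal-variance two-sided t-test p-value
#' is below `alpha` (default 0.05, the conventional 95% confidence level).
#' Features with zero variance in both classes carry no signal and are
#' excluded up front; their names are attached as attribute `excluded`.
#'
#' @param data Feature tibble (optionally with an `id` column) or matrix.
#' @param labels Binary class vector (+1/-1, or sensitizer/non-sensitizer).
#' @param alpha Significance level in (0, 1).
#' @return Character vector of selected feature names.
#' @export
select_by_ttest <- function(data, labels, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  x <- as_feature_matrix(data)
  y <- binary_labels(labels)
  if (min(table(y)) < 2) {
    abort("Each class needs at least 2 members for the t-test",
          class = "skinqsar_degenerate_input_error")
  }
  a <- x[y == 1, , drop = FALSE]
  b <- x[y == -1, , drop = FALSE]
  zero_var <- matrixStats_colVar(a) == 0 & matrixStats_colVar(b) == 0
  testable <- colnames(x)[!zero_var]
  pvals <- vapply(testable, function(f) {
    stats::t.test(a[, f], b[, f], var.equal = FALSE,
                  alternative = "two.sided")$p.value
  }, numeric(1))
  selected <- testable[!is.na(pvals) & pvals < alpha]
  attr(selected, "excluded") <- colnames(x)[zero_var]
  selected
}

# column variances without an extra dependency
matrixStats_colVar <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  colSums((m - rep(mu, each = n))^2) / (n - 1)
}

#' CFS merit of a feature subset
#'
#' Correlation-based feature selection merit
#' \deqn{M_S = \frac{k \, \bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}}}
#' with \eqn{k} the subset size, \eqn{\bar r_{cf}} the mean absolute
#' feature-class correlation (point-biserial against the binary class) and
#' \eqn{\bar r_{ff}} the mean absolute pairwise feature-feature Pearson
#' correlation. High merit rewards class-relevant, mutually independent
#' features. Zero-variance features contribute correlation 0.
#'
#' @param subset Character vector of feature names (non-empty).
#' @param data Feature tibble or matrix.
#' @param labels Binary class vector.
#' @return Non-negative merit.
#' @export
cfs_merit <- function(subset, data, labels) {
  if (length(subset) == 0) {
    abort("Feature subset must be non-empty", class = "skinqsar_value_error")
  }
  x <- as_feature_matrix(data)
  stopifnot(all(subset %in% colnames(x)))
  y <- binary_labels(labels)
  x <- x[, subset, drop = FALSE]
  k <- length(subset)
  safe_cor <- function(u, v) {
    r <- suppressWarnings(stats::cor(u, v))
    if (is.na(r)) 0 else r
  }
  r_cf <- mean(abs(vapply(seq_len(k), function(j) safe_cor(x[, j], y), 0)))
  r_ff <- if (k == 1) 0 else {
    cm <- suppressWarnings(stats::cor(x))
    cm[is.na(cm)] <- 0
    mean(abs(cm[upper.tri(cm)]))
  }
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

#' Best-first CFS subset search
#'
#' Forward best-first search over feature subsets maximizing [cfs_merit()]:
#' starting from the empty set, the open list is expanded at the
#' highest-merit node by adding one feature at a time, and the search stops
#' after `stale_limit` consecutive expansions that fail to improve the best
#' merit found. Ties break lexicographically by feature name, making the
#' search deterministic.
#'
#' @param data Feature tibble or matrix.
#' @param labels Binary class vector.
#' @param candidates Feature names to search over (non-empty).
#' @param stale_limit Consecutive non-improving expansions before stopping.
#' @return [feature_set()] named `"reduced"` holding the best subset found.
#' @export
reduce_best_first <- function(data, labels, candidates, stale_limit = 5) {
  if (length(candidates) == 0) {
    abort("Candidate feature list must be non-empty",
          class = "skinqsar_value_error")
  }
  x <- as_feature_matrix(data)
  stopifnot(all(candidates %in% colnames(x)))
  y <- binary_labels(labels)
  if (min(table(y)) < 2) {
    abort("Each class needs at least 2 members",
          class = "skinqsar_degenerate_input_error")
  }
  candidates <- sort(unique(candidates))

  # cache correlations once; cached_merit reproduces cfs_merit exactly
  xc <- x[, candidates, drop = FALSE]
  safe_cor_vec <- suppressWarnings(stats::cor(xc, y))
  safe_cor_vec[is.na(safe_cor_vec)] <- 0
  rcf <- abs(as.numeric(safe_cor_vec))
  names(rcf) <- candidates
  rff <- abs(suppressWarnings(stats::cor(xc)))
  rff[is.na(rff)] <- 0
  cached_merit <- function(feats) {
    k <- length(feats)
    m_cf <- mean(rcf[feats])
    m_ff <- if (k == 1) 0 else {
      sub <- rff[feats, feats]
      mean(sub[upper.tri(sub)])
    }
    k * m_cf / sqrt(k + k * (k - 1) * m_ff)
  }

  key_of <- function(feats) {
    if (length(feats) == 0) "<empty>" else paste(feats, collapse = "|")
  }
  # open list: named merit vector, names are subset keys
  open_merit <- c("<empty>" = 0)
  open_feats <- list("<empty>" = character(0))
  seen <- new.env(parent = emptyenv())
  assign("<empty>", TRUE, envir = seen)

  best_feats <- character(0)
  best_merit <- -Inf
  stale <- 0

  while (stale < stale_limit && length(open_merit) > 0) {
    # pop the best node (ties: lexicographically smallest key)
    ord <- order(-open_merit, names(open_merit))
    pick <- names(open_merit)[ord[1]]
    node <- open_feats[[pick]]
    open_merit <- open_merit[names(open_merit) != pick]
    open_feats[[pick]] <- NULL

    improved <- FALSE
    for (f in setdiff(candidates, node)) {
      child <- sort(c(node, f))
      ck <- key_of(child)
      if (!is.null(seen[[ck]])) next
      assign(ck, TRUE, envir = seen)
      m <- cached_merit(child)
      open_merit[ck] <- m
      open_feats[[ck]] <- child
      if (m > best_merit + 1e-10) {
        best_merit <- m
        best_feats <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
  }
  feature_set("reduced", best_feats,
              recipe = paste0("best-first CFS over ", length(candidates),
                              " candidates"),
              merit = best_merit)
}

#' Construct a feature set
#'
#' @param name Set name (e.g. `"set-1"`).
#' @param features Ordered, unique feature names (non-empty).
#' @param recipe Textual provenance.
#' @param merit Optional CFS merit.
#' @return Object of class `feature_set`.
#' @export
feature_set <- function(name, features, recipe = NA_character_, merit = NA_real_) {
  if (length(features) == 0) {
    abort("A feature set must be non-empty", class = "skinqsar_value_error")
  }
  structure(
    list(name = name, features = unique(features), recipe = recipe,
         merit = merit),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set ", x$name, "> ", length(x$features), " features",
      if (!is.na(x$merit)) paste0(", merit ", signif(x$merit, 4)) else "",
      "\n  recipe: ", x$recipe, "\n", sep = "")
  invisible(x)
}

#' Assemble one of the five descriptor-set combinations
#'
#' The five recipes combine the statistically screened descriptors `A`, the
#' skin-protein reactive-group fingerprint bits `B` and the literature
#' mechanism bits `C`:
#' * set-1: `reduce(A + B)` — joint CFS reduction of A and B;
#' * set-2: `reduce(A) + B` — all of B kept (literature-derived bits are
#'   never discarded), A reduced;
#' * set-3: `reduce(A) + C` — all of C kept, A reduced;
#' * set-4: `reduce(A) + reduce(B)` — both reduced independently;
#' * set-5: `A + B + C` — everything, no reduction.
#' C is never reduced in any recipe.
#'
#' @param set_id Integer 1..5.
#' @param A,B,C Character vectors of feature names drawn from `data`.
#' @param data Feature tibble or matrix containing all of A, B, C.
#' @param labels Binary class vector.
#' @param stale_limit Passed to [reduce_best_first()].
#' @return [feature_set()] named `"set-<id>"`.
#' @export
build_descriptor_set <- function(set_id, A, B, C, data, labels,
                                 stale_limit = 5) {
  if (!set_id %in% 1:5) {
    abort("set_id must be 1..5", class = "skinqsar_value_error")
  }
  red <- function(feats) reduce_best_first(data, labels, feats, stale_limit)$features
  feats <- switch(as.character(set_id),
    "1" = red(union(A, B)),
    "2" = union(red(A), B),
    "3" = union(red(A), C),
    "4" = union(red(A), if (length(B) > 0) red(B) else character(0)),
    "5" = union(union(A, B), C)
  )
  recipe <- switch(as.character(set_id),
    "1" = "reduce(A + B)", "2" = "reduce(A) + B", "3" = "reduce(A) + C",
    "4" = "reduce(A) + reduce(B)", "5" = "A + B + C")
  feature_set(paste0("set-", set_id), feats, recipe = recipe)
}
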