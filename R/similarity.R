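# Structural-similarity component: hashed linear-path fingerprints (FP2,
# paths of 1-7 bonds hashed into 1024 bits) and Tanimoto coefficients against
# a labeled reference set.

#' Path-based fingerprints for a molecule table
#'
#' Computes 1024-bit hashed linear-path (FP2) fingerprints. Identical
#' canonical structures yield identical bit sets.
#'
#' @param mols Molecule tibble.
#' @param type OpenBabel fingerprint name, default `"FP2"` (pluggable).
#' @return Integer 0/1 matrix, one row per molecule (rownames = id).
#' @export
fingerprint_matrix <- function(mols, type = "FP2") {
  conv <- mols_to_sdf(mols)
  fp <- ChemmineR::fingerprintOB(conv$sdf, type)
  m <- fp@fpma  # FPset bit matrix slot
  out <- matrix(0L, nrow = nrow(mols), ncol = ncol(m),
                dimnames = list(mols$id, colnames(m)))
  out[conv$valid, ] <- as.integer(m)
  out
}

#' Tanimoto coefficient of two fingerprints
#'
#' `|a AND b| / |a OR b|` over bit sets; defined as 1 when both fingerprints
#' are empty (two featureless structures are maximally similar).
#'
#' @param a,b Numeric/logical 0/1 vectors of equal length.
#' @return Coefficient in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Fingerprint lengths differ", class = "skinqsar_length_mismatch_error")
  }
  a <- as.logical(a)
  b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0) return(1)
  sum(a & b) / union
}

#' Pairwise Tanimoto matrix
#'
#' @param x Fingerprint matrix (rows = molecules).
#' @param y Optional second matrix; defaults to `x`.
#' @return Numeric matrix of coefficients, `nrow(x)` by `nrow(y)`.
#' @export
tanimoto_matrix <- function(x, y = NULL) {
  y <- y %||% x
  if (ncol(x) != ncol(y)) {
    abort("Fingerprint lengths differ", class = "skinqsar_length_mismatch_error")
  }
  inter <- x %*% t(y)
  union <- outer(rowSums(x), rowSums(y), `+`) - inter
  out <- inter / union
  out[union == 0] <- 1  # both-empty convention
  out
}

similarity_direction <- function(score, best, cutoff) {
  if (best < cutoff) "NoMatch" else if (score > 0) "S" else if (score < 0) "N" else "NS"
}

#' Similarity component votes
#'
#' Screens each test molecule against a labeled reference set. A molecule
#' whose best Tanimoto coefficient falls below `cutoff` scores 0 (direction
#' `NoMatch`); otherwise it scores `+1` when every maximal-coefficient
#' neighbor is a sensitizer, `-1` when every one is a non-sensitizer, and 0
#' when both classes attain the maximum (direction `NS`). A best coefficient
#' of 1 triggers an InChIKey identity check and records the confirmed match.
#'
#' @param tests Molecule tibble of test molecules.
#' @param reference Labeled molecule tibble (any potency class except `N`
#'   counts as sensitizer).
#' @param cutoff Tanimoto cutoff, default 0.6; a coefficient exactly at the
#'   cutoff passes.
#' @param reference_fp Optional precomputed [fingerprint_matrix()] of
#'   `reference`.
#' @return Tibble with one row per test molecule: `id`, `score` (-1/0/+1),
#'   `direction` (`S`, `N`, `NS`, `NoMatch`), `best_coefficient`,
#'   `identical_match` (reference id or `NA`), `neighbors` (list-column of
#'   reference neighbors at or above the cutoff, sorted by coefficient).
#' @export
similarity_scores <- function(tests, reference, cutoff = 0.6,
                              reference_fp = NULL) {
  if (nrow(reference) == 0) {
    abort("Reference set is empty", class = "skinqsar_empty_reference_error")
  }
  ref_fp <- reference_fp %||% fingerprint_matrix(reference)
  test_fp <- fingerprint_matrix(tests)
  sim <- tanimoto_matrix(test_fp, ref_fp)
  ref_sens <- is_sensitizer(reference$potency)

  purrr::map_dfr(seq_len(nrow(tests)), function(i) {
    s <- sim[i, ]
    best <- max(s)
    neighbors <- tibble(
      ref_id = reference$id,
      ref_class = ifelse(ref_sens, "sensitizer", "non-sensitizer"),
      coefficient = unname(s)
    ) |>
      filter(.data$coefficient >= cutoff) |>
      arrange(desc(.data$coefficient), .data$ref_id)

    if (best < cutoff) {
      score <- 0L
    } else {
      at_max <- abs(s - best) < 1e-12
      any_s <- any(ref_sens[at_max])
      any_n <- any(!ref_sens[at_max])
      score <- if (any_s && any_n) 0L else if (any_s) 1L else -1L
    }

    identical_match <- NA_character_
    if (best >= 1 - 1e-12) {
      cand <- which(abs(s - best) < 1e-12)
      conf <- cand[reference$inchikey[cand] == tests$inchikey[i]]
      if (length(conf) > 0) identical_match <- reference$id[conf[1]]
    }

    tibble(
      id = tests$id[i],
      score = score,
      direction = similarity_direction(score, best, cutoff),
      best_coefficient = best,
      identical_match = identical_match,
      neighbors = list(neighbors)
    )
  })
}

#' Similarity verdict for a single molecule
#'
#' @inheritParams similarity_scores
#' @param test One-row molecule tibble.
#' @return One-row tibble (see [similarity_scores()]).
#' @export
similarity_component <- function(test, reference, cutoff = 0.6,
                                 reference_fp = NULL) {
  similarity_scores(test[1, , drop = FALSE], reference, cutoff, reference_fp)
}
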