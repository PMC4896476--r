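# Synthetic benchmark generator: desk-scale labeled molecule sets in which
# sensitizers carry planted electrophilic sub-structures grafted onto a
# fixed pool of simple drug-like scaffolds, plus Gaussian descriptor tables
# with class-separated means for exercising selection and classification.

# Scaffolds: rings + short chains, chosen so that no scaffold (nor any inert
# decoration) matches an alert in the built-in library; every SMILES ends in
# an atom with free valence so suffix concatenation grafts a substituent.
SCAFFOLD_POOL <- c(
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "COc1ccccc1", "CC(C)c1ccccc1",
  "CC(C)(C)c1ccccc1", "CN(C)c1ccccc1", "c1ccncc1", "Cc1ccncc1", "c1cncnc1",
  "c1ccoc1", "c1ccsc1", "c1ccc2ccccc2c1", "c1ccc(cc1)c1ccccc1",
  "C1CCCCC1", "CC1CCCCC1", "C1CCCC1", "C1CCNCC1", "C1CCOC1", "O1CCOCC1",
  "C1COCCN1", "C1Cc2ccccc2C1", "C1CCc2ccccc2C1", "CCCCCC", "CCCCCCCC",
  "CCOCC", "CCN(CC)CC", "CCCOCCC", "CC(C)OC(C)C", "CCCCN"
)

# Inert decorations appended between scaffold and (for sensitizers) the
# reactive fragment; none creates an alert match.
INERT_SUFFIXES <- c("", "C", "CC", "CCC", "CCCC", "OC", "OCC", "CO", "N(C)C")

# Reactive fragment grafted per plantable alert; each fragment is built to
# match its alert's SMARTS once attached.
ALERT_FRAGMENTS <- c(
  michael_acceptor_carbonyl = "C=CC(C)=O",
  michael_acceptor_nitrile = "C=CC#N",
  michael_acceptor_nitro = "C=C[N+](=O)[O-]",
  aldehyde = "CC=O",
  alpha_dicarbonyl = "C(=O)C(C)=O",
  acyl_halide = "CC(=O)Cl",
  anhydride = "CC(=O)OC(C)=O",
  primary_alkyl_halide = "CCBr",
  sulfonate_ester = "COS(C)(=O)=O",
  epoxide = "CC1CO1",
  snar_halo_nitroarene_ortho = "c1ccc(Cl)c([N+](=O)[O-])c1",
  isocyanate = "CN=C=O",
  isothiocyanate = "CN=C=S",
  hydroperoxide = "COO",
  alpha_halo_carbonyl = "CC(=O)CCl",
  maleimide = "CN1C(=O)C=CC1=O",
  quinone = "CC1=CC(=O)C=CC1=O"
)

DEFAULT_PLANTED <- c(
  "michael_acceptor_carbonyl", "aldehyde", "acyl_halide",
  "primary_alkyl_halide", "epoxide", "snar_halo_nitroarene_ortho",
  "isocyanate", "sulfonate_ester"
)

# Parent-pool-like defaults: sensitizer prevalence and potency mix follow
# the 543-molecule labeled pool (X 17, St 32, S 180, M 90, W 74, N 150).
DEFAULT_POTENCY_MIX <- c(X = 17, St = 32, S = 180, M = 90, W = 74) / 393

#' Specification for a synthetic benchmark
#'
#' @param n Total molecule count.
#' @param prevalence Sensitizer fraction in (0, 1); default follows the
#'   labeled parent pool (393/543).
#' @param planted_alerts Alert ids from the library to embed in sensitizers;
#'   must be plantable (see `skinqsar:::ALERT_FRAGMENTS`).
#' @param potency_mix Proportions over `X`, `St`, `S`, `M`, `W` (normalized
#'   internally).
#' @param seed Integer RNG seed.
#' @return Object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n = 400, prevalence = 393 / 543,
                           planted_alerts = DEFAULT_PLANTED,
                           potency_mix = DEFAULT_POTENCY_MIX,
                           seed = DEFAULT_SEED) {
  stopifnot(n >= 2, prevalence > 0, prevalence < 1)
  if (is.null(names(potency_mix)) ||
      !setequal(names(potency_mix), c("X", "St", "S", "M", "W"))) {
    abort("potency_mix must be named over X, St, S, M, W",
          class = "skinqsar_value_error")
  }
  potency_mix <- potency_mix / sum(potency_mix)
  structure(
    list(n = n, prevalence = prevalence, planted_alerts = planted_alerts,
         potency_mix = potency_mix, seed = seed),
    class = "benchmark_spec"
  )
}

# Largest-remainder apportionment: integer counts summing to n, proportional
# to p.
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(-(raw - base), seq_along(raw))[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Generate a synthetic labeled benchmark
#'
#' Sensitizers are built by grafting a planted reactive fragment (sampled
#' from `spec$planted_alerts`) onto a randomly sampled scaffold, optionally
#' through an inert linker; non-sensitizers use the same scaffolds and
#' linkers without reactive fragments. Every generated SMILES is validated,
#' every sensitizer is verified to match its planted alert, every
#' non-sensitizer is verified to match no alert in the library, and
#' structures are unique by InChIKey. Generation is reproducible under the
#' spec's seed; a graft that cannot produce valid, distinct chemistry within
#' bounded retries raises `skinqsar_generation_error`.
#'
#' @param spec [benchmark_spec()].
#' @param library Alert tibble resolving all `spec$planted_alerts`.
#' @return Labeled molecule tibble with attribute `planted_alert` (named by
#'   molecule id).
#' @export
generate_benchmark <- function(spec, library = default_alert_library()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  unresolved <- setdiff(spec$planted_alerts, library$id)
  if (length(unresolved) > 0) {
    abort(paste0("Planted alert(s) not in library: ",
                 paste(unresolved, collapse = ", ")),
          class = "skinqsar_value_error")
  }
  unplantable <- setdiff(spec$planted_alerts, names(ALERT_FRAGMENTS))
  if (length(unplantable) > 0) {
    abort(paste0("No graft fragment for alert(s): ",
                 paste(unplantable, collapse = ", ")),
          class = "skinqsar_value_error")
  }

  n_sens <- round(spec$n * spec$prevalence)
  n_non <- spec$n - n_sens
  potency_counts <- apportion(n_sens, spec$potency_mix)

  withr::with_seed(spec$seed, {
    # Draw candidate SMILES in rounds, batch-validating chemistry, alert
    # content and InChIKey uniqueness; bounded retries (10 rounds).
    build_set <- function(n_needed, sensitizer, taken_keys = character(0)) {
      out_smiles <- character(0)
      out_alert <- character(0)
      seen_keys <- taken_keys
      for (round in seq_len(10)) {
        if (length(out_smiles) >= n_needed) break
        m <- max(2 * (n_needed - length(out_smiles)), 20)
        scaffold <- sample(SCAFFOLD_POOL, m, replace = TRUE)
        linker <- sample(INERT_SUFFIXES, m, replace = TRUE)
        if (sensitizer) {
          alert_id <- sample(spec$planted_alerts, m, replace = TRUE)
          smi <- paste0(scaffold, linker, ALERT_FRAGMENTS[alert_id])
        } else {
          alert_id <- rep(NA_character_, m)
          smi <- paste0(scaffold, linker,
                        strrep("C", sample.int(4, m, replace = TRUE) - 1))
        }
        valid <- smiles_is_valid(smi)
        smi <- smi[valid]
        alert_id <- alert_id[valid]
        if (length(smi) == 0) next
        cand <- tibble(id = paste0("cand", seq_along(smi)), smiles = smi)
        counts <- alert_match_counts(cand, library)
        keep <- if (sensitizer) {
          counts[cbind(seq_along(smi), match(alert_id, library$id))] > 0
        } else {
          rowSums(counts) == 0
        }
        smi <- smi[keep]
        alert_id <- alert_id[keep]
        if (length(smi) == 0) next
        keys <- inchikey(smi)
        fresh <- !is.na(keys) & !keys %in% seen_keys & !duplicated(keys)
        seen_keys <- c(seen_keys, keys[fresh])
        out_smiles <- c(out_smiles, smi[fresh])
        out_alert <- c(out_alert, alert_id[fresh])
      }
      if (length(out_smiles) < n_needed) {
        abort("Could not generate enough valid, unique molecules",
              class = "skinqsar_generation_error")
      }
      list(smiles = out_smiles[seq_len(n_needed)],
           alert = out_alert[seq_len(n_needed)],
           keys = setdiff(seen_keys, taken_keys)[seq_len(n_needed)])
    }

    sens <- build_set(n_sens, sensitizer = TRUE)
    non <- build_set(n_non, sensitizer = FALSE, taken_keys = sens$keys)

    df <- tibble(
      id = c(sprintf("sens_%04d", seq_len(n_sens)),
             sprintf("nons_%04d", seq_len(n_non))),
      smiles = c(sens$smiles, non$smiles),
      potency = c(rep(names(potency_counts), potency_counts),
                  rep("N", n_non)),
      source = "synthetic-benchmark"
    )
    out <- parse_molecules(df)
    attr(out, "planted_alert") <- stats::setNames(
      c(sens$alert, rep(NA_character_, n_non)), df$id)
    attr(out, "name") <- "synthetic-benchmark"
    out
  })
}

#' Generate a synthetic descriptor table
#'
#' Two balanced Gaussian classes: `n_informative` features carry a
#' standardized class-mean gap of `effect` (in units of the within-class
#' standard deviation), the remaining features are pure noise.
#'
#' @param n_per_class Molecules per class.
#' @param p_features Total feature count.
#' @param n_informative Features with a planted class effect
#'   (`<= p_features`).
#' @param effect Standardized mean difference (>= 0).
#' @param seed Integer RNG seed.
#' @return List with `data` (tibble: `id` + features `f0001`...),
#'   `labels` (+1/-1) and `informative` (feature names carrying signal).
#' @export
generate_descriptor_table <- function(n_per_class, p_features, n_informative,
                                      effect, seed = DEFAULT_SEED) {
  stopifnot(n_per_class >= 2, p_features >= 1, effect >= 0)
  if (n_informative > p_features) {
    abort("n_informative exceeds p_features", class = "skinqsar_value_error")
  }
  n <- 2 * n_per_class
  labels <- rep(c(1, -1), each = n_per_class)
  feature_names <- sprintf("f%04d", seq_len(p_features))
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * p_features), nrow = n,
                dimnames = list(NULL, feature_names))
    if (n_informative > 0) {
      x[labels == 1, seq_len(n_informative)] <-
        x[labels == 1, seq_len(n_informative)] + effect
    }
  })
  list(
    data = bind_cols(tibble(id = sprintf("m%04d", seq_len(n))), as_tibble(x)),
    labels = labels,
    informative = feature_names[seq_len(n_informative)]
  )
}
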