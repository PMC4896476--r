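# Structural alerts: SMARTS patterns for skin-protein reactive groups
# (electrophilic reaction domains: Michael addition, Schiff base formation,
# acyl transfer, SN2, SNAr, ...). The engine is pattern-agnostic; patterns
# are data supplied via CSV/YAML.

probe_sdf <- function() {
  # tiny molecule used only to force SMARTS compilation
  smiles_to_sdf_one("CCO", "probe")
}

compile_check <- function(id, smarts, probe) {
  ok <- tryCatch({
    ChemmineR::smartsSearchOB(probe, smarts, uniqueMatches = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort(paste0("Invalid SMARTS for alert '", id, "': ", smarts),
          class = "skinqsar_invalid_smarts_error")
  }
  invisible(TRUE)
}

validate_alert_library <- function(lib) {
  lib <- as_tibble(lib)
  required <- c("id", "smarts", "mechanism")
  if (!all(required %in% names(lib))) {
    abort("Alert library needs columns id, smarts, mechanism",
          class = "skinqsar_format_error")
  }
  if (!"source" %in% names(lib)) lib$source <- NA_character_
  if (!"set" %in% names(lib)) lib$set <- NA_character_
  dup <- lib$id[duplicated(lib$id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate alert id(s): ", paste(unique(dup), collapse = ", ")),
          class = "skinqsar_duplicate_id_error")
  }
  probe <- probe_sdf()
  purrr::walk2(lib$id, lib$smarts, compile_check, probe = probe)
  lib
}

#' Load a SMARTS alert library
#'
#' Reads alert definitions from CSV (columns `id`, `smarts`, `mechanism`,
#' optional `source`, `set`) or YAML (a list of records with the same fields).
#' Every pattern is compiled on load; an uncompilable pattern raises
#' `skinqsar_invalid_smarts_error` naming the offending id, and a repeated id
#' raises `skinqsar_duplicate_id_error`. File order is preserved.
#'
#' @param path CSV or YAML file.
#' @return Alert tibble.
#' @seealso [default_alert_library()]
#' @export
load_alert_library <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "skinqsar_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  lib <- if (ext %in% c("yml", "yaml")) {
    entries <- yaml::read_yaml(path)
    purrr::map_dfr(entries, function(e) tibble(
      id = e$id, smarts = e$smarts, mechanism = e$mechanism,
      source = e$source %||% NA_character_, set = e$set %||% NA_character_
    ))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_alert_library(lib)
}

#' Built-in skin-protein reactive-group alert library
#'
#' Curated SMARTS encodings of the canonical electrophilic reaction domains
#' (Michael acceptors, Schiff-base-forming carbonyls, acyl-transfer agents,
#' SN2 alkylating agents, SNAr-activated haloaromatics, and related
#' literature mechanisms). Column `set` marks skin-protein reactive-group
#' fingerprints (`B`) versus additional literature mechanism patterns (`C`).
#' Any library with the same columns can be dropped in via
#' [load_alert_library()].
#'
#' @return Alert tibble.
#' @export
default_alert_library <- function() {
  load_alert_library(system.file("extdata", "alert_library.csv",
                                 package = "skinqsar"))
}

# Match-count matrix: molecules x alerts (unique-atom-set match counts).
alert_match_counts <- function(mols, library) {
  conv <- mols_to_sdf(mols)
  counts <- matrix(0L, nrow = nrow(mols), ncol = nrow(library),
                   dimnames = list(mols$id, library$id))
  for (j in seq_len(nrow(library))) {
    hits <- ChemmineR::smartsSearchOB(conv$sdf, library$smarts[j],
                                      uniqueMatches = TRUE)
    counts[conv$valid, j] <- as.integer(hits)
  }
  counts
}

#' Binary alert fingerprints
#'
#' One 0/1 column per alert id: does the molecule contain the pattern?
#' These columns serve as the sub-structure fingerprint feature groups in
#' QSAR descriptor sets.
#'
#' @param mols Molecule tibble.
#' @param library Alert tibble (default: built-in library).
#' @return Tibble: `id` plus one integer 0/1 column per alert.
#' @export
alert_fingerprints <- function(mols, library = default_alert_library()) {
  counts <- alert_match_counts(mols, library)
  bind_cols(tibble(id = mols$id), as_tibble(1L * (counts > 0)))
}

#' Sub-structure component vote for one molecule
#'
#' Scores `+1` when any alert pattern matches and `-1` otherwise — absence of
#' a reactive group argues against skin-protein binding, so it counts as
#' evidence for non-sensitizer rather than as no evidence. All matching
#' alerts are reported with their mechanism and unique-atom-set match count.
#'
#' @param mol One-row molecule tibble.
#' @param library Alert tibble.
#' @return One-row tibble: `id`, `score` (+1/-1), `matches` (list-column
#'   tibble of `alert_id`, `mechanism`, `n_matches`).
#' @export
substructure_component <- function(mol, library = default_alert_library()) {
  substructure_scores(mol[1, , drop = FALSE], library)
}

#' Sub-structure component votes for many molecules
#'
#' Vectorized form of [substructure_component()].
#'
#' @inheritParams substructure_component
#' @param mols Molecule tibble.
#' @return Tibble with one row per molecule.
#' @export
substructure_scores <- function(mols, library = default_alert_library()) {
  if (nrow(library) == 0) {
    abort("Alert library is empty", class = "skinqsar_empty_library_error")
  }
  counts <- alert_match_counts(mols, library)
  matches <- purrr::map(seq_len(nrow(mols)), function(i) {
    hit <- which(counts[i, ] > 0)
    tibble(
      alert_id = library$id[hit],
      mechanism = library$mechanism[hit],
      n_matches = unname(counts[i, hit])
    )
  })
  tibble(
    id = mols$id,
    score = unname(ifelse(rowSums(counts > 0) > 0, 1L, -1L)),
    matches = matches
  )
}
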