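#' @import dplyr
#' @import tibble
#' @importFrom rlang abort warn .data
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#' @importFrom stats predict setNames
NULL

# Potency vocabulary: Extreme, Strong, unknown-potency Sensitizer, Moderate,
# Weak, Non-sensitizer, plus UNKNOWN for unlabeled prediction-time molecules.
POTENCY_LEVELS <- c("X", "St", "S", "M", "W", "N", "UNKNOWN")
SENSITIZER_CLASSES <- c("X", "St", "S", "M", "W")

#' Is a potency class a sensitizer class?
#'
#' Any potency class except `N` (non-sensitizer) and `UNKNOWN` counts as a
#' sensitizer.
#'
#' @param potency Character vector of potency classes.
#' @return Logical vector.
#' @export
is_sensitizer <- function(potency) {
  potency %in% SENSITIZER_CLASSES
}

check_potency <- function(potency) {
  bad <- setdiff(unique(potency), POTENCY_LEVELS)
  if (length(bad) > 0) {
    abort(
      paste0(
        "Unknown potency label(s): ", paste(bad, collapse = ", "),
        ". Allowed: ", paste(POTENCY_LEVELS, collapse = ", ")
      ),
      class = "skinqsar_label_error"
    )
  }
  invisible(potency)
}

# ---- OpenBabel-backed structure helpers -------------------------------------

trim_ob <- function(x) {
  x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  vapply(x, function(line) strsplit(line, "\t", fixed = TRUE)[[1]][1], "",
         USE.NAMES = FALSE)
}

# Batch-convert SMILES through OpenBabel; returns NA for entries the toolkit
# cannot parse. OpenBabel "repairs" some malformed strings during format
# conversion, so validity is decided by smiles_is_valid(), not here.
ob_convert <- function(smiles, to) {
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  res <- tryCatch(
    trim_ob(ChemmineOB::convertFormat("SMI", to, paste(smiles[ok], collapse = "\n"))),
    error = function(e) NULL
  )
  if (!is.null(res) && length(res) == sum(ok)) {
    out[ok] <- res
    return(out)
  }
  # Batch failed or dropped entries: fall back to per-molecule conversion.
  out[ok] <- vapply(smiles[ok], function(s) {
    tryCatch(trim_ob(ChemmineOB::convertFormat("SMI", to, s))[1],
             error = function(e) NA_character_)
  }, "", USE.NAMES = FALSE)
  out
}

canonical_smiles <- function(smiles) ob_convert(smiles, "CAN")

inchikey <- function(smiles) ob_convert(smiles, "INCHIKEY")

# One molecule -> SDF, NULL when unparsable/invalid.
smiles_to_sdf_one <- function(smiles, id = "mol") {
  if (is.na(smiles) || !nzchar(smiles)) return(NULL)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, id))),
    error = function(e) NULL
  )
  if (is.null(sdf)) return(NULL)
  ok <- tryCatch(ChemmineR::validSDF(sdf), error = function(e) FALSE)
  if (!isTRUE(ok[1])) return(NULL)
  sdf
}

#' Check SMILES validity
#'
#' A SMILES string is valid when OpenBabel parses it into a sane molecule
#' (balanced branches and ring bonds, known atom symbols, at least one atom).
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector, `FALSE` for unparsable entries.
#' @export
smiles_is_valid <- function(smiles) {
  vapply(seq_along(smiles), function(i) {
    !is.null(smiles_to_sdf_one(smiles[i], paste0("m", i)))
  }, logical(1))
}

# Batch SMILES vector -> SDFset for the valid subset, plus validity mask.
mols_to_sdf <- function(mols) {
  stopifnot(all(c("id", "smiles") %in% names(mols)))
  ids <- make.unique(mols$id)
  ok <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(mols$smiles, ids)))
    as.logical(ChemmineR::validSDF(sdf))
  }, error = function(e) smiles_is_valid(mols$smiles))
  if (!any(ok)) abort("No valid molecules to convert", class = "skinqsar_parse_error")
  sdfset <- suppressWarnings(
    ChemmineR::smiles2sdf(setNames(mols$smiles[ok], ids[ok]))
  )
  vs <- as.logical(ChemmineR::validSDF(sdfset))
  if (!all(vs)) {
    sdfset <- sdfset[vs]
    ok[which(ok)[!vs]] <- FALSE
  }
  list(sdf = sdfset, valid = ok)
}

# ---- Molecule records -------------------------------------------------------

new_molecule_tbl <- function(id, cas, smiles_input, smiles, key, potency, source) {
  tibble(
    id = as.character(id),
    cas = as.character(cas),
    smiles_input = as.character(smiles_input),
    smiles = as.character(smiles),
    inchikey = as.character(key),
    potency = as.character(potency),
    source = as.character(source)
  )
}

#' Parse a single molecule from SMILES
#'
#' Canonicalizes the structure and derives its InChIKey. Invalid SMILES raise
#' a parse error (condition class `skinqsar_parse_error`), potency labels
#' outside the vocabulary a label error (`skinqsar_label_error`).
#'
#' @param smiles SMILES string.
#' @param id Molecule identifier (preserved verbatim).
#' @param potency Potency class, one of `X`, `St`, `S`, `M`, `W`, `N`,
#'   `UNKNOWN` (default for prediction-time molecules).
#' @param cas Optional CAS registry number.
#' @param source Optional free-text provenance tag.
#' @return One-row tibble with columns `id`, `cas`, `smiles_input`, `smiles`
#'   (canonical), `inchikey`, `potency`, `source`.
#' @examples
#' parse_molecule("CCO", "ethanol", potency = "N")
#' @export
parse_molecule <- function(smiles, id, potency = "UNKNOWN", cas = NA_character_,
                           source = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  check_potency(potency)
  if (!nzchar(smiles) || !smiles_is_valid(smiles)) {
    abort(paste0("Cannot parse SMILES for '", id, "': ", smiles),
          class = "skinqsar_parse_error")
  }
  can <- canonical_smiles(smiles)
  key <- inchikey(smiles)
  if (is.na(can) || is.na(key)) {
    abort(paste0("Structure conversion failed for '", id, "'"),
          class = "skinqsar_parse_error")
  }
  new_molecule_tbl(id, cas, smiles, can, key, potency, source)
}

#' Parse many molecules, skipping invalid entries
#'
#' Vectorized companion to [parse_molecule()]: rows whose SMILES fail to parse
#' are dropped with a warning; the skipped count is attached as attribute
#' `n_skipped`.
#'
#' @param df Data frame with columns `smiles` and `id`; optional `cas`,
#'   `potency`, `source`.
#' @return Tibble of molecule records (see [parse_molecule()]).
#' @export
parse_molecules <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("id", "smiles") %in% names(df)))
  if (!"cas" %in% names(df)) df$cas <- NA_character_
  if (!"potency" %in% names(df)) df$potency <- "UNKNOWN"
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$potency[is.na(df$potency) | !nzchar(df$potency)] <- "UNKNOWN"
  check_potency(df$potency)

  valid <- smiles_is_valid(df$smiles)
  n_skipped <- sum(!valid)
  if (n_skipped > 0) {
    warn(paste0("Skipped ", n_skipped, " molecule(s) that failed SMILES parsing: ",
                paste(utils::head(df$id[!valid], 5), collapse = ", "),
                if (n_skipped > 5) ", ..." else ""))
  }
  kept <- df[valid, , drop = FALSE]
  out <- new_molecule_tbl(
    kept$id, kept$cas, kept$smiles,
    canonical_smiles(kept$smiles), inchikey(kept$smiles),
    kept$potency, kept$source
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Are two molecule records the same structure?
#'
#' Identity is decided by full 27-character InChIKey equality (not prefix
#' matching), so stereoisomers with differing keys are distinct.
#'
#' @param a,b One-row molecule tibbles with `inchikey` populated.
#' @return Logical scalar.
#' @export
is_identical <- function(a, b) {
  ka <- a$inchikey[1]
  kb <- b$inchikey[1]
  stopifnot(!is.na(ka), !is.na(kb))
  identical(ka, kb)
}

#' Tabulate potency classes
#'
#' @param mols Molecule tibble.
#' @return Tibble with columns `potency` and `n`.
#' @export
class_counts <- function(mols) {
  mols |>
    count(.data$potency, name = "n") |>
    arrange(match(.data$potency, POTENCY_LEVELS))
}

# Dataset invariants: unique inchikey, unique non-empty CAS (conflict between
# same CAS / different structure is an error; same structure is deduplicated).
validate_dataset <- function(mols) {
  cas_tbl <- mols |>
    filter(!is.na(.data$cas), nzchar(.data$cas)) |>
    distinct(.data$cas, .data$inchikey)
  dup_cas <- cas_tbl |> count(.data$cas) |> filter(.data$n > 1)
  if (nrow(dup_cas) > 0) {
    abort(paste0("CAS number(s) shared by different structures: ",
                 paste(dup_cas$cas, collapse = ", ")),
          class = "skinqsar_duplicate_error")
  }
  out <- mols |> distinct(.data$inchikey, .keep_all = TRUE)
  n_dropped <- nrow(mols) - nrow(out)
  if (n_dropped > 0) {
    warn(paste0("Dropped ", n_dropped, " duplicate structure(s) by InChIKey"))
  }
  out
}

#' Load a labeled molecule dataset
#'
#' Reads a SMILES line list, a CSV table, or an SDF (V2000) file into a
#' molecule tibble. Records failing SMILES parsing are skipped with a warning
#' and counted in attribute `n_skipped`; duplicate structures (by InChIKey)
#' are deduplicated. Two rows sharing a CAS number but encoding different
#' structures raise a `skinqsar_duplicate_error`.
#'
#' CSV dialect: UTF-8 with a header row; columns `id` and `smiles` required,
#' `cas`, `potency`, `source` optional. SMILES lists are whitespace-separated
#' `smiles id [potency]` lines. SDF potency is read from a named property
#' field (`potency_field`).
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"csv"`, `"smiles"`, `"sdf"`.
#' @param potency_field SDF property holding the potency class.
#' @param name Dataset name (attribute), defaults to the file name.
#' @return Molecule tibble with attributes `name` and `n_skipped`.
#' @export
read_molecules <- function(path, format = c("auto", "csv", "smiles", "sdf"),
                           potency_field = "potency", name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "skinqsar_format_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", smi = "smiles", smiles = "smiles", txt = "smiles",
      sdf = "sdf", mol = "sdf",
      abort(paste0("Cannot infer format from extension: ", path),
            class = "skinqsar_format_error")
    )
  }
  df <- switch(format,
    csv = {
      raw <- tryCatch(
        readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
        error = function(e) abort(paste0("Unreadable CSV: ", path),
                                  class = "skinqsar_format_error")
      )
      if (!all(c("id", "smiles") %in% names(raw))) {
        abort("CSV must declare 'id' and 'smiles' columns",
              class = "skinqsar_format_error")
      }
      raw
    },
    smiles = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0) {
        abort(paste0("Empty SMILES file: ", path), class = "skinqsar_format_error")
      }
      parts <- strsplit(trimws(lines), "[[:space:]]+")
      tibble(
        smiles = vapply(parts, `[`, "", 1),
        id = vapply(parts, function(p) {
          if (length(p) >= 2) p[2] else NA_character_
        }, ""),
        potency = vapply(parts, function(p) {
          if (length(p) >= 3) p[3] else "UNKNOWN"
        }, "")
      ) |>
        mutate(id = ifelse(is.na(.data$id), paste0("mol", row_number()), .data$id))
    },
    sdf = {
      sdfset <- tryCatch(
        suppressWarnings(ChemmineR::read.SDFset(path)),
        error = function(e) abort(paste0("Unreadable SDF: ", path),
                                  class = "skinqsar_format_error")
      )
      ok <- ChemmineR::validSDF(sdfset)
      sdfset <- sdfset[ok]
      smi <- as.character(ChemmineR::sdf2smiles(sdfset))
      blocks <- ChemmineR::datablock(sdfset)
      get_prop <- function(b, field) {
        if (length(b) == 0 || !field %in% names(b)) NA_character_ else unname(b[field])
      }
      tibble(
        id = vapply(ChemmineR::SDFset2SDF(sdfset), function(x)
          ChemmineR::header(x)[["Molecule_Name"]], ""),
        smiles = smi[seq_along(sdfset)],
        cas = vapply(blocks, get_prop, "", field = "cas"),
        potency = dplyr::coalesce(vapply(blocks, get_prop, "",
                                         field = potency_field), "UNKNOWN")
      )
    }
  )
  out <- parse_molecules(df)
  out <- validate_dataset(out)
  attr(out, "name") <- name %||% basename(path)
  out
}

#' Write molecules to disk
#'
#' @param mols Molecule tibble.
#' @param path Output path.
#' @param format `"csv"` (full record table) or `"smiles"`
#'   (`smiles id potency` lines).
#' @return `path`, invisibly.
#' @export
write_molecules <- function(mols, path, format = c("csv", "smiles")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(mols, path)
  } else {
    writeLines(paste(mols$smiles, mols$id, mols$potency), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
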