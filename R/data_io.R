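#' Read a circRNA-drug association table
#'
#' Reads a tab-separated edge list with three columns: circRNA id, drug id and
#' a 0/1 label (1 = observed sensitivity association, 0 = known or assumed
#' non-association). A header line is auto-detected: if the third field of the
#' first row is not numeric the row is treated as a header.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `circ_id`, `drug_id`, `label`.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) abort(sprintf("Association file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = "ccc",
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warn("Association file is empty; returning an empty table.")
    return(tibble::tibble(circ_id = character(), drug_id = character(),
                          label = integer()))
  }
  bad <- which(is.na(raw[[1]]) | is.na(raw[[2]]) | is.na(raw[[3]]))
  if (length(bad) > 0) {
    abort(sprintf("Malformed association row (expected 3 columns) at line %d.",
                  bad[1]))
  }
  # header if the third field is non-numeric
  if (is.na(suppressWarnings(as.numeric(raw[[3]][1])))) {
    raw <- raw[-1, , drop = FALSE]
    if (nrow(raw) == 0) {
      warn("Association file contains only a header; returning an empty table.")
      return(tibble::tibble(circ_id = character(), drug_id = character(),
                            label = integer()))
    }
  }
  lab_num <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(lab_num) | !lab_num %in% c(0, 1))
  if (length(bad) > 0) {
    abort(sprintf("Label outside {0,1} at data line %d: '%s'",
                  bad[1], raw[[3]][bad[1]]))
  }
  tbl <- tibble::tibble(circ_id = raw[[1]], drug_id = raw[[2]],
                        label = as.integer(lab_num))
  validate_associations(tbl)
  tbl
}

validate_associations <- function(tbl) {
  if (any(!nzchar(tbl$circ_id)) || any(!nzchar(tbl$drug_id))) {
    abort("Association ids must be non-empty strings.")
  }
  key <- paste(tbl$circ_id, tbl$drug_id, sep = "\t")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    abort(sprintf("Duplicate circRNA-drug pair: %s",
                  gsub("\t", " / ", d, fixed = TRUE)))
  }
  invisible(tbl)
}

#' Read circRNA sequences from a FASTA file
#'
#' Sequence ids are the FASTA headers up to the first whitespace. Because the
#' k-mer featurizer works in DNA space, `U` is normalized to `T` on read.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector mapping circRNA id to sequence.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA header: %s", ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) {
    abort(sprintf("Empty sequence for id '%s'.", ids[!nzchar(seqs)][1]))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("Sequence '%s' contains characters outside {A,C,G,T,U,N}.",
                  ids[bad][1]))
  }
  setNames(seqs, ids)
}

#' Read a drug SMILES table
#'
#' @param path Path to a TSV file of (drug_id, SMILES), optional header
#'   auto-detected when the first row's second field equals "smiles"
#'   case-insensitively.
#' @return A named character vector mapping drug id to SMILES string.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) abort(sprintf("SMILES file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = "cc",
                         progress = FALSE)
  if (nrow(raw) == 0) return(setNames(character(), character()))
  if (ncol(raw) < 2) abort("Malformed SMILES table: expected 2 columns.")
  bad <- which(is.na(raw[[1]]) | is.na(raw[[2]]) | !nzchar(raw[[2]]))
  if (length(bad) > 0) {
    abort(sprintf("Malformed SMILES row (expected 2 non-empty columns) at line %d.",
                  bad[1]))
  }
  if (tolower(raw[[2]][1]) == "smiles") raw <- raw[-1, , drop = FALSE]
  if (anyDuplicated(raw[[1]])) {
    abort(sprintf("Duplicate drug id: %s", raw[[1]][duplicated(raw[[1]])][1]))
  }
  setNames(raw[[2]], raw[[1]])
}

#' Write ranked association predictions
#'
#' Writes a TSV of scored circRNA-drug pairs sorted by descending score with a
#' deterministic lexicographic `(circ_id, drug_id)` tie-break, so identical
#' inputs always produce byte-identical files.
#'
#' @param predictions A data frame with columns `circ_id`, `drug_id`, `score`.
#' @param path Output path.
#' @return The input (sorted), invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("circ_id", "drug_id", "score") %in% names(predictions)))
  if (nrow(predictions) > 0 && any(!is.finite(predictions$score))) {
    abort("Prediction scores must be finite.")
  }
  out <- dplyr::arrange(tibble::as_tibble(predictions),
                        dplyr::desc(.data$score), .data$circ_id, .data$drug_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Write cross-validation metrics as JSON
#'
#' @param cv A `cda_cv` object from [cda_cv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(cv, path) {
  stopifnot(inherits(cv, "cda_cv"))
  per_fold <- tidy(cv)
  summary <- glance(cv)
  jsonlite::write_json(
    list(folds = per_fold, summary = summary, seed = cv$config$seed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
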