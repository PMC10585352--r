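#' Read protein sequences from FASTA
#'
#' Sequences are uppercased; the header token before the first whitespace
#' becomes the id. Coordinates throughout the package are 1-based inclusive
#' (UniProt convention).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence` (possibly zero rows).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(tibble::tibble(id = character(0), sequence = character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA contains an entry with an empty id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("FASTA contains an empty sequence")
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  set <- Biostrings::AAStringSet(sequences$sequence)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read span annotations and validate them against sequences
#'
#' The annotation table is tab-separated with columns `id`, `start`, `end`,
#' `class` and optionally `evidence` (e.g. a ProRule identifier); coordinates
#' are 1-based inclusive. Rows whose coordinates are inverted or fall outside
#' the referenced sequence are rejected with a warning; rows referencing an
#' unknown id are reported as orphans with a warning. Both are dropped from
#' the result.
#'
#' @param path Path to the TSV (header row required).
#' @param sequences Tibble with `id`, `sequence` as from [read_fasta()].
#' @return Tibble with columns `id`, `start`, `end`, `class`, `evidence`.
#' @export
read_annotations <- function(path, sequences) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("id", "start", "end", "class")
  if (!all(required %in% names(ann)))
    stop("annotation table must have columns: ", paste(required, collapse = ", "))
  if (!"evidence" %in% names(ann)) ann$evidence <- NA_character_
  ann <- tibble::tibble(
    id = ann$id,
    start = as.integer(ann$start),
    end = as.integer(ann$end),
    class = ann$class,
    evidence = ann$evidence
  )
  validate_annotations(ann, sequences)
}

# Internal: drop invalid/orphan annotation rows with warnings.
validate_annotations <- function(ann, sequences) {
  seq_len_of <- stats::setNames(nchar(sequences$sequence), sequences$id)
  orphan <- !(ann$id %in% sequences$id)
  if (any(orphan))
    warning("annotation rows reference unknown sequence id(s): ",
            paste(unique(ann$id[orphan]), collapse = ", "), call. = FALSE)
  ann2 <- ann[!orphan, , drop = FALSE]
  bad_coord <- is.na(ann2$start) | is.na(ann2$end) |
    ann2$start < 1L | ann2$start > ann2$end |
    ann2$end > unname(seq_len_of[ann2$id])
  if (any(bad_coord))
    warning(sum(bad_coord), " annotation row(s) rejected: coordinates invalid ",
            "or outside the sequence", call. = FALSE)
  ann2[!bad_coord, , drop = FALSE]
}


#' Write an annotation table
#'
#' @param annotations Tibble with `id`, `start`, `end`, `class` and optionally
#'   `evidence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("id", "start", "end", "class") %in% names(annotations)))
  if (!"evidence" %in% names(annotations))
    annotations$evidence <- NA_character_
  readr::write_tsv(annotations[, c("id", "start", "end", "class", "evidence")],
                   path)
  invisible(path)
}

#' Write predicted spans (and optionally marginals) to disk
#'
#' Predictions go to a TSV with columns `id`, `start`, `end`, `class`
#' (1-based inclusive). If per-position class marginals are supplied, a
#' companion TSV is written with columns `id`, `position` and one column per
#' class, probabilities rounded to 4 decimals.
#'
#' @param spans Tibble with `id`, `start`, `end`, `class`.
#' @param path Output TSV path for the spans.
#' @param marginals Optional named list of `marginal_profile` matrices (or
#'   plain matrices with class columns), keyed by sequence id.
#' @param marginals_path Path for the companion marginals file; required when
#'   `marginals` is given.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(spans, path, marginals = NULL,
                              marginals_path = NULL) {
  stopifnot(all(c("id", "start", "end", "class") %in% names(spans)))
  readr::write_tsv(spans[, c("id", "start", "end", "class")], path)
  if (!is.null(marginals)) {
    if (is.null(marginals_path))
      stop("marginals_path is required when marginals are supplied")
    long <- purrr::imap(marginals, function(m, id) {
      m <- round(unclass(m), 4)
      dplyr::bind_cols(
        tibble::tibble(id = id, position = seq_len(nrow(m))),
        tibble::as_tibble(m)
      )
    })
    readr::write_tsv(dplyr::bind_rows(long), marginals_path)
  }
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path Path to the TSV.
#' @return Tibble with `id`, `start`, `end`, `class`.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           class = readr::col_character()
                         ))
  tibble::as_tibble(out)
}

#' Bundle sequences and annotations into one dataset object
#'
#' A light container pairing the sequence table with its annotation table;
#' all data-preparation filters take and return it, so they chain with the
#' pipe.
#'
#' @param sequences Tibble with `id`, `sequence`.
#' @param annotations Tibble with `id`, `start`, `end`, `class`, optionally
#'   `evidence`; defaults to an empty table.
#' @return An object of class `peptide_dataset`.
#' @export
peptide_dataset <- function(sequences, annotations = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  if (anyDuplicated(sequences$id))
    stop("sequence ids must be unique")
  if (is.null(annotations))
    annotations <- tibble::tibble(id = character(0), start = integer(0),
                                  end = integer(0), class = character(0),
                                  evidence = character(0))
  if (!"evidence" %in% names(annotations))
    annotations$evidence <- NA_character_
  structure(list(sequences = tibble::as_tibble(sequences),
                 annotations = tibble::as_tibble(annotations)),
            class = "peptide_dataset")
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat("<peptide_dataset> ", nrow(x$sequences), " sequence(s), ",
      nrow(x$annotations), " annotation(s)\n", sep = "")
  invisible(x)
}
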