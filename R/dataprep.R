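#' Filter annotations by span length
#'
#' Keeps only Peptide/Propeptide annotations whose length lies in
#' `[min_len, max_len]` (5-50 by default, the range that covers the large
#' majority of curated peptide annotations) and drops every sequence left
#' without any in-range span annotation. Signal/Transit/Chain annotations are
#' untouched by the length rule but cannot keep a sequence alive on their own.
#'
#' @param dataset A [peptide_dataset()].
#' @param min_len,max_len Length bounds in residues.
#' @return A filtered `peptide_dataset`.
#' @export
filter_length <- function(dataset, min_len = 5L, max_len = 50L) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  ann <- dataset$annotations
  span_cls <- ann$class %in% c("Peptide", "Propeptide")
  len <- ann$end - ann$start + 1L
  keep <- !span_cls | (len >= min_len & len <= max_len)
  ann <- ann[keep, , drop = FALSE]
  alive <- unique(ann$id[ann$class %in% c("Peptide", "Propeptide")])
  peptide_dataset(
    dataset$sequences[dataset$sequences$id %in% alive, , drop = FALSE],
    ann[ann$id %in% alive, , drop = FALSE]
  )
}

#' Discard precursors whose peptide covers the whole mature protein
#'
#' A peptide spanning the entire sequence — or the entire mature region
#' downstream of a Signal/Transit annotation that starts at position 1 — is
#' not a cleavage product of a precursor, so the whole sequence is dropped.
#'
#' @param dataset A [peptide_dataset()].
#' @return A filtered `peptide_dataset`.
#' @export
filter_full_coverage <- function(dataset) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  seqs <- dataset$sequences
  ann <- dataset$annotations
  seq_len_of <- stats::setNames(nchar(seqs$sequence), seqs$id)
  drop_id <- character(0)
  for (id in seqs$id) {
    T_ <- unname(seq_len_of[id])
    a <- ann[ann$id == id, , drop = FALSE]
    mature_start <- 1L
    sig <- a[a$class %in% c("Signal", "Transit") & a$start == 1L, , drop = FALSE]
    if (nrow(sig) > 0L) mature_start <- max(sig$end) + 1L
    pep <- a[a$class %in% c("Peptide", "Propeptide"), , drop = FALSE]
    full <- (pep$start == 1L & pep$end == T_) |
      (pep$start == mature_start & pep$end == T_)
    if (any(full)) drop_id <- c(drop_id, id)
  }
  peptide_dataset(
    seqs[!seqs$id %in% drop_id, , drop = FALSE],
    ann[!ann$id %in% drop_id, , drop = FALSE]
  )
}

#' Remove propeptides flagged as sorting signals by ProRule evidence
#'
#' Drops Propeptide annotations whose evidence tag matches one of the excluded
#' ProRule identifiers (by default PRU00477 and PRU01070, which mark sorting
#' signals rather than cleaved propeptides). Other annotations on the same
#' sequence survive; a sequence left without span annotations is removed later
#' by [filter_length()].
#'
#' @param dataset A [peptide_dataset()].
#' @param excluded_evidence_tags Character vector of evidence tags to drop.
#' @return A filtered `peptide_dataset`.
#' @export
filter_prorule_propeptides <- function(dataset,
                                       excluded_evidence_tags = c("PRU00477",
                                                                  "PRU01070")) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  ann <- dataset$annotations
  drop <- ann$class == "Propeptide" &
    !is.na(ann$evidence) & ann$evidence %in% excluded_evidence_tags
  peptide_dataset(dataset$sequences, ann[!drop, , drop = FALSE])
}

#' Extract the flanking motifs of each span annotation
#'
#' The residues immediately outside a peptide's termini carry the protease
#' cleavage signal (e.g. dibasic KR/RR convertase sites). For each
#' Peptide/Propeptide annotation this returns the `n` residues before the
#' start (`n_flank`) and the `n` after the end (`c_flank`); positions beyond
#' the sequence termini are padded with the boundary token `"*"`.
#'
#' @param dataset A [peptide_dataset()].
#' @param n Flank width in residues (default 2).
#' @return Tibble with `id`, `start`, `end`, `class`, `n_flank`, `c_flank`.
#' @export
extract_flanking_motifs <- function(dataset, n = 2L) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  n <- as.integer(n)
  seqs <- stats::setNames(dataset$sequences$sequence, dataset$sequences$id)
  ann <- dataset$annotations
  ann <- ann[ann$class %in% c("Peptide", "Propeptide"), , drop = FALSE]
  flank <- function(seq, from, to) {
    T_ <- nchar(seq)
    chars <- vapply(from:to, function(p) {
      if (p < 1L || p > T_) "*" else substr(seq, p, p)
    }, character(1))
    paste(chars, collapse = "")
  }
  n_flank <- character(nrow(ann))
  c_flank <- character(nrow(ann))
  for (k in seq_len(nrow(ann))) {
    seq <- unname(seqs[ann$id[k]])
    n_flank[k] <- flank(seq, ann$start[k] - n, ann$start[k] - 1L)
    c_flank[k] <- flank(seq, ann$end[k] + 1L, ann$end[k] + n)
  }
  tibble::tibble(id = ann$id, start = ann$start, end = ann$end,
                 class = ann$class, n_flank = n_flank, c_flank = c_flank)
}

#' Default per-residue embedding table for motif clustering
#'
#' Each amino acid is represented by its BLOSUM62 similarity row against the
#' 20 standard amino acids; the boundary token `"*"` uses its own BLOSUM62
#' row. Any table mapping tokens to fixed-width vectors (e.g. language-model
#' token embeddings) can be supplied instead.
#'
#' @return Numeric matrix, one row per token, 20 columns.
#' @export
blosum_embedding_table <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B <- data_env$BLOSUM62
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  tokens <- c(aas, "B", "Z", "X", "*")
  out <- B[tokens, aas]
  storage.mode(out) <- "double"
  out
}

#' Embed flanking motifs and cluster them with k-means
#'
#' Each motif's four flank residues (two N-terminal, two C-terminal) are
#' mapped through the embedding table and concatenated into one vector;
#' k-means (k-means++-style multi-start via `nstart`) groups the motifs so
#' that fold assignment can balance cleavage-motif types across folds. k = 50
#' is the default operating point.
#'
#' @param motifs Tibble from [extract_flanking_motifs()].
#' @param embedding_table Token-by-dimension matrix with rownames; defaults to
#'   [blosum_embedding_table()]. Tokens absent from the table map to zero
#'   vectors.
#' @param k Number of clusters (default 50); reduced with a warning if fewer
#'   distinct motif vectors exist.
#' @param seed Integer seed for the k-means restarts.
#' @return The input tibble with an integer `cluster` column (1..k).
#' @export
embed_and_cluster_motifs <- function(motifs, embedding_table = NULL, k = 50L,
                                     seed = 1L) {
  if (is.null(embedding_table)) embedding_table <- blosum_embedding_table()
  D <- ncol(embedding_table)
  embed_token <- function(tok) {
    if (tok %in% rownames(embedding_table)) embedding_table[tok, ] else rep(0, D)
  }
  X <- t(vapply(seq_len(nrow(motifs)), function(i) {
    toks <- c(strsplit(motifs$n_flank[i], "")[[1]],
              strsplit(motifs$c_flank[i], "")[[1]])
    unlist(lapply(toks, embed_token))
  }, numeric(4L * D)))
  n_distinct <- nrow(unique(X))
  k <- as.integer(k)
  if (k > n_distinct) {
    warning("k reduced from ", k, " to ", n_distinct,
            " (number of distinct motif vectors)", call. = FALSE)
    k <- n_distinct
  }
  cl <- withr::with_seed(as.integer(seed), {
    if (k == 1L) list(cluster = rep(1L, nrow(X)))
    else stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)
  })
  dplyr::mutate(motifs, cluster = as.integer(cl$cluster))
}

#' Cluster-stratified fold assignment
#'
#' Each sequence is tagged with the majority cluster of its span annotations;
#' within each cluster, sequences are shuffled and dealt round-robin over the
#' folds, so every cluster spreads as evenly as possible (per-cluster fold
#' counts differ by at most 1). This is the no-dependency fallback for
#' homology-aware partitioning; an externally produced partition can be loaded
#' with [read_partition()] instead.
#'
#' @param clustered_motifs Tibble from [embed_and_cluster_motifs()] (needs
#'   `id` and `cluster`).
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for the within-cluster shuffles.
#' @return An object of class `fold_assignment`: tibble with `id`, `cluster`
#'   (the record's majority cluster) and `fold` (0-based).
#' @export
assign_folds_stratified <- function(clustered_motifs, k_folds = 5L, seed = 1L) {
  k_folds <- as.integer(k_folds)
  if (is.na(k_folds) || k_folds < 2L) stop("k_folds must be at least 2")
  per_record <- clustered_motifs |>
    dplyr::count(.data$id, .data$cluster) |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("id", "cluster")
  out <- withr::with_seed(as.integer(seed), {
    per_record |>
      dplyr::group_by(.data$cluster) |>
      dplyr::group_modify(function(df, key) {
        df <- df[sample.int(nrow(df)), , drop = FALSE]
        df$fold <- (seq_len(nrow(df)) - 1L) %% k_folds
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::select("id", "cluster", "fold")
  })
  structure(tibble::as_tibble(out), class = c("fold_assignment",
                                              class(tibble::tibble())))
}

#' Load an externally produced fold partition
#'
#' Hook for homology-partitioning tools: a TSV with columns `id` and `fold`.
#'
#' @param path Path to the TSV.
#' @return Tibble with `id` and integer `fold`.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           fold = readr::col_integer()
                         ))
  if (!all(c("id", "fold") %in% names(out)))
    stop("partition file must have columns id and fold")
  tibble::as_tibble(out)
}

#' Enumerate the nested cross-validation model plan
#'
#' With `k` outer folds, each outer (test) fold leaves `k - 1` candidate
#' validation folds, giving `k * (k - 1)` models (20 for the default 5-fold
#' scheme); each model trains on the remaining `k - 2` folds. Ensembling at
#' prediction time combines all of them.
#'
#' @param k_folds Number of outer folds (default 5).
#' @return Tibble with `model`, `test_fold`, `val_fold` and a list-column
#'   `train_folds`.
#' @export
nested_cv_plan <- function(k_folds = 5L) {
  k_folds <- as.integer(k_folds)
  if (k_folds < 3L) stop("nested cross-validation needs at least 3 folds")
  folds <- 0:(k_folds - 1L)
  grid <- expand.grid(test_fold = folds, val_fold = folds)
  grid <- grid[grid$test_fold != grid$val_fold, , drop = FALSE]
  grid <- grid[order(grid$test_fold, grid$val_fold), , drop = FALSE]
  tibble::tibble(
    model = seq_len(nrow(grid)),
    test_fold = grid$test_fold,
    val_fold = grid$val_fold,
    train_folds = purrr::map2(grid$test_fold, grid$val_fold,
                              function(a, b) setdiff(folds, c(a, b)))
  )
}
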