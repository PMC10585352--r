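mk_dataset <- function(lens, spans) {
  # lens: named sequence lengths; spans: tibble(id, start, end, class, evidence)
  seqs <- tibble::tibble(id = names(lens),
                         sequence = vapply(lens, function(L)
                           paste(rep("A", L), collapse = ""), character(1)))
  peptide_dataset(seqs, spans)
}

test_that("length filter keeps 5-50 spans inclusively and drops empty records", {
  # span lengths 4, 5, 50, 51 -> exactly the 5 and 50 survive
  ds <- mk_dataset(c(X = 130L), tibble::tibble(
    id = "X", start = c(1L, 10L, 20L, 75L), end = c(4L, 14L, 69L, 125L),
    class = "Peptide", evidence = NA_character_))
  out <- filter_length(ds)
  expect_equal(out$annotations$end - out$annotations$start + 1L, c(5L, 50L))

  only_long <- mk_dataset(c(Y = 80L), tibble::tibble(
    id = "Y", start = 10L, end = 69L, class = "Propeptide",
    evidence = NA_character_))
  expect_equal(nrow(filter_length(only_long)$sequences), 0L)

  empty <- mk_dataset(c(Z = 10L)[0], tibble::tibble(
    id = character(0), start = integer(0), end = integer(0),
    class = character(0), evidence = character(0)))
  expect_equal(nrow(filter_length(empty)$sequences), 0L)
})

test_that("full-coverage peptides drop the record, with and without a signal", {
  full <- mk_dataset(c(A = 30L), tibble::tibble(
    id = "A", start = 1L, end = 30L, class = "Peptide",
    evidence = NA_character_))
  expect_equal(nrow(filter_full_coverage(full)$sequences), 0L)

  mature <- mk_dataset(c(B = 30L), tibble::tibble(
    id = "B", start = c(1L, 23L), end = c(22L, 30L),
    class = c("Signal", "Peptide"), evidence = NA_character_))
  expect_equal(nrow(filter_full_coverage(mature)$sequences), 0L)

  partial <- mk_dataset(c(C = 30L), tibble::tibble(
    id = "C", start = c(1L, 23L), end = c(22L, 29L),
    class = c("Signal", "Peptide"), evidence = NA_character_))
  expect_equal(nrow(filter_full_coverage(partial)$sequences), 1L)
})

test_that("ProRule-flagged propeptides are removed, others kept", {
  ds <- mk_dataset(c(A = 100L), tibble::tibble(
    id = "A", start = c(5L, 30L, 60L), end = c(20L, 45L, 75L),
    class = c("Propeptide", "Propeptide", "Peptide"),
    evidence = c("PRU00477", NA, "PRU00477")))
  out <- filter_prorule_propeptides(ds)
  # only the evidence-matching Propeptide goes; the Peptide keeps its row
  expect_equal(nrow(out$annotations), 2L)
  expect_true(all(out$annotations$start %in% c(30L, 60L)))
})

test_that("filters are idempotent and order-independent where stated", {
  ds <- mk_dataset(c(A = 100L, B = 40L), tibble::tibble(
    id = c("A", "A", "B", "B"), start = c(5L, 30L, 1L, 11L),
    end = c(20L, 45L, 40L, 20L),
    class = c("Propeptide", "Peptide", "Peptide", "Peptide"),
    evidence = c("PRU01070", NA, NA, NA)))
  f1 <- filter_length(ds)
  expect_equal(filter_length(f1), f1)
  f2 <- filter_full_coverage(ds)
  expect_equal(filter_full_coverage(f2), f2)
  f3 <- filter_prorule_propeptides(ds)
  expect_equal(filter_prorule_propeptides(f3), f3)
  ab <- filter_full_coverage(filter_prorule_propeptides(ds))
  ba <- filter_prorule_propeptides(filter_full_coverage(ds))
  expect_equal(ab, ba)
})

test_that("flanking motifs index the right residues and pad at boundaries", {
  seqs <- tibble::tibble(id = "M", sequence = "MKKRGLPFRRAA")
  ann <- tibble::tibble(id = "M", start = 5L, end = 8L, class = "Peptide",
                        evidence = NA_character_)
  out <- extract_flanking_motifs(peptide_dataset(seqs, ann))
  expect_equal(out$n_flank, "KR")
  expect_equal(out$c_flank, "RR")

  edge <- tibble::tibble(id = "M", start = c(1L, 8L), end = c(4L, 12L),
                         class = "Peptide", evidence = NA_character_)
  out2 <- extract_flanking_motifs(peptide_dataset(seqs, edge))
  expect_equal(out2$n_flank[1], "**")
  expect_equal(out2$c_flank[2], "**")
  # one-off boundary: start 2 -> one pad + first residue
  off <- tibble::tibble(id = "M", start = 2L, end = 6L, class = "Peptide",
                        evidence = NA_character_)
  expect_equal(extract_flanking_motifs(peptide_dataset(seqs, off))$n_flank,
               "*M")
})

test_that("motif clustering separates two distinct motif populations", {
  set.seed(41)
  n <- 60
  mk <- function(nf, cf, id0) tibble::tibble(
    id = paste0(id0, seq_len(n)), start = 10L, end = 20L, class = "Peptide",
    n_flank = nf, c_flank = cf)
  motifs <- dplyr::bind_rows(mk("KR", "RR", "a"), mk("GG", "LL", "b"))
  out <- embed_and_cluster_motifs(motifs, k = 2, seed = 1)
  tab <- table(out$cluster, rep(c("KR", "GG"), each = n))
  agreement <- max(sum(diag(tab)), sum(tab[2:1, cbind(1:2)])) / (2 * n)
  expect_gte(agreement, 0.95)
})

test_that("identical motifs land in one cluster however many were requested", {
  motifs <- tibble::tibble(id = paste0("r", 1:10), start = 5L, end = 15L,
                           class = "Peptide", n_flank = "KR", c_flank = "RR")
  expect_warning(out <- embed_and_cluster_motifs(motifs, k = 50, seed = 1),
                 "reduced")
  expect_equal(length(unique(out$cluster)), 1L)
})

test_that("stratified folds balance every cluster to within one record", {
  set.seed(43)
  motifs <- tibble::tibble(
    id = paste0("r", 1:100), start = 10L, end = 20L, class = "Peptide",
    n_flank = "KR", c_flank = "RR",
    cluster = sample(1:7, 100, replace = TRUE))
  fa <- assign_folds_stratified(motifs, k_folds = 5, seed = 2)
  expect_equal(sort(unique(fa$fold)), 0:4)
  expect_equal(nrow(fa), 100L)
  per_cluster <- table(fa$cluster, fa$fold)
  expect_true(all(apply(per_cluster, 1, function(x) diff(range(x))) <= 1))

  # single cluster, 100 records, 5 folds -> exactly 20 each
  one <- dplyr::mutate(motifs, cluster = 1L)
  fa1 <- assign_folds_stratified(one, k_folds = 5, seed = 2)
  expect_true(all(table(fa1$fold) == 20))
  expect_error(assign_folds_stratified(one, k_folds = 1), "at least 2")
})

test_that("partition files round trip through the external-partition hook", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = c("A", "B"), fold = c(0L, 3L)), f)
  out <- read_partition(f)
  expect_equal(out$fold, c(0L, 3L))
})

test_that("the nested cross-validation plan enumerates k*(k-1) models", {
  plan <- nested_cv_plan(5)
  expect_equal(nrow(plan), 20L)
  expect_true(all(plan$test_fold != plan$val_fold))
  expect_true(all(vapply(seq_len(20), function(i)
    length(plan$train_folds[[i]]) == 3L &&
      !plan$test_fold[i] %in% plan$train_folds[[i]] &&
      !plan$val_fold[i] %in% plan$train_folds[[i]], logical(1))))
})
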