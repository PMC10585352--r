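test_that("class-label runs and state paths convert to spans correctly", {
  lbl <- c("None", "None", "Peptide", "Peptide", "Peptide", "Peptide",
           "Peptide", "None")
  expect_equal(spans_from_labels(lbl),
               tibble::tibble(start = 3L, end = 7L, class = "Peptide"))
  expect_equal(nrow(spans_from_labels(rep("None", 5))), 0L)

  # back-to-back state spans stay distinct under the state-path form
  sp <- build_state_space(5, 50, c("Peptide", "Propeptide"))
  p <- function(k) state_index(sp, "Peptide", k)
  path <- c(sapply(1:5, p), sapply(1:5, p))
  spans <- spans_from_labels(path, sp)
  expect_equal(spans$start, c(1L, 6L))
  expect_equal(spans$end, c(5L, 10L))
  # whereas the merged class labels would fuse them into one run
  expect_equal(nrow(spans_from_labels(sp$class_of_state[path])), 1L)
})

test_that("overlap groups are connected components, transitively closed", {
  spans <- tibble::tibble(start = c(1L, 5L, 30L), end = c(10L, 14L, 40L))
  g <- collapse_overlap_groups(spans)
  expect_equal(g$group, c(1L, 1L, 2L))

  chain <- tibble::tibble(start = c(1L, 8L, 18L), end = c(10L, 20L, 30L))
  expect_equal(collapse_overlap_groups(chain)$group, rep(1L, 3))

  disjoint <- tibble::tibble(start = c(1L, 20L), end = c(5L, 30L))
  expect_equal(collapse_overlap_groups(disjoint)$group, 1:2)

  # same coordinates, different classes -> different groups
  two_cls <- tibble::tibble(start = c(1L, 1L), end = c(10L, 10L),
                            class = c("Peptide", "Propeptide"))
  expect_equal(length(unique(collapse_overlap_groups(two_cls)$group)), 2L)
})

test_that("tolerance-window matching counts TP/FP/FN as specified", {
  truth <- tibble::tibble(start = 10L, end = 20L)
  pred <- tibble::tibble(start = 12L, end = 18L)
  expect_equal(match_spans(pred, truth, 3)[, 1:3],
               tibble::tibble(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(match_spans(pred, truth, 1)[, 1:3],
               tibble::tibble(tp = 0L, fp = 1L, fn = 1L))
  # duplicate prediction onto an already-matched group is a false positive
  dup <- tibble::tibble(start = c(10L, 11L), end = c(20L, 21L))
  expect_equal(match_spans(dup, truth, 3)[, 1:3],
               tibble::tibble(tp = 1L, fp = 1L, fn = 0L))
  expect_error(match_spans(pred, truth, -1), "tolerance")
})

test_that("greedy matching agrees with the exhaustive matching oracle", {
  set.seed(17)
  mismatches <- 0L
  for (rep in 1:150) {
    n_t <- sample(0:4, 1)
    n_p <- sample(0:4, 1)
    truth <- tibble::tibble(start = sample(1:40, n_t, replace = TRUE))
    truth$end <- truth$start + sample(5:12, max(n_t, 1))[seq_len(n_t)]
    pred <- tibble::tibble(start = sample(1:40, n_p, replace = TRUE))
    pred$end <- pred$start + sample(5:12, max(n_p, 1))[seq_len(n_p)]
    tol <- sample(0:4, 1)
    got <- match_spans(pred, truth, tol)
    want <- oracle_max_matching(pred, truth, tol)
    if (got$tp != want$tp) mismatches <- mismatches + 1L
    # greedy can only lose TPs relative to the optimum, never invent them
    expect_lte(got$tp, want$tp)
    expect_equal(got$tp + got$fn,
                 want$tp + want$fn)  # group count is invariant
  }
  # on these instances greedy should essentially always match the optimum
  expect_lte(mismatches, 2L)
})

test_that("precision/recall/F1 follow the closed forms and conventions", {
  m <- precision_recall_f1(tibble::tibble(tp = 1L, fp = 1L, fn = 1L))
  expect_equal(c(m$precision, m$recall, m$f1), c(0.5, 0.5, 0.5))
  m0 <- precision_recall_f1(tibble::tibble(tp = 0L, fp = 0L, fn = 5L))
  expect_equal(c(m0$precision, m0$recall, m0$f1), c(0, 0, 0))
  m2 <- precision_recall_f1(tibble::tibble(tp = 3L, fp = 1L, fn = 2L))
  expect_equal(c(m2$precision, m2$recall, m2$f1), c(0.75, 0.6, 2 / 3))
})

test_that("probability thresholding extracts maximal segments inclusively", {
  expect_equal(segments_from_probabilities(c(0.1, 0.6, 0.7, 0.2, 0.9)),
               tibble::tibble(start = c(2L, 5L), end = c(3L, 5L)))
  expect_equal(nrow(segments_from_probabilities(c(0.1, 0.4))), 0L)
  expect_equal(segments_from_probabilities(c(0.5, 0.5))$end, 2L)  # >= threshold
  expect_error(segments_from_probabilities(0.4, threshold = 0), "threshold")
})

test_that("TP is monotone non-decreasing and FP+FN non-increasing in tolerance", {
  set.seed(23)
  for (rep in 1:40) {
    n_t <- sample(1:5, 1); n_p <- sample(1:5, 1)
    truth <- tibble::tibble(start = sample(1:60, n_t))
    truth$end <- truth$start + sample(5:15, n_t, replace = TRUE)
    pred <- tibble::tibble(start = sample(1:60, n_p))
    pred$end <- pred$start + sample(5:15, n_p, replace = TRUE)
    res <- lapply(0:5, function(tol) match_spans(pred, truth, tol))
    tp <- vapply(res, function(r) r$tp, integer(1))
    err <- vapply(res, function(r) r$fp + r$fn, integer(1))
    expect_true(all(diff(tp) >= 0))
    expect_true(all(diff(err) <= 0))
  }
})

test_that("matching is invariant under coordinate translation", {
  set.seed(29)
  truth <- tibble::tibble(start = c(5L, 30L), end = c(15L, 44L))
  pred <- tibble::tibble(start = c(6L, 33L), end = c(14L, 41L))
  a <- match_spans(pred, truth, 3)
  b <- match_spans(dplyr::mutate(pred, start = start + 100L, end = end + 100L),
                   dplyr::mutate(truth, start = start + 100L, end = end + 100L),
                   3)
  expect_equal(a, b)
})

test_that("dataset evaluation pools counts, averages replicates, flags gaps", {
  truth <- tibble::tibble(id = c("A", "A", "B"), start = c(10L, 30L, 5L),
                          end = c(20L, 40L, 14L),
                          class = c("Peptide", "Propeptide", "Peptide"))
  pred <- dplyr::bind_rows(
    tibble::tibble(replicate = 1L, id = "A", start = 10L, end = 20L,
                   class = "Peptide"),
    tibble::tibble(replicate = 2L, id = c("A", "B"), start = c(10L, 5L),
                   end = c(20L, 14L), class = "Peptide")
  )
  expect_warning(ev <- evaluate_dataset(pred, truth, tolerances = 0),
                 "false negatives")
  pep <- ev$replicates[ev$replicates$class == "Peptide", ]
  expect_equal(pep$recall, c(0.5, 1))
  s <- ev$summary[ev$summary$class == "Peptide", ]
  expect_equal(s$recall_mean, 0.75)
  expect_equal(s$recall_sd, 0.25)  # population SD over two replicates

  # perfect predictions give 1 everywhere, single replicate has SD 0
  perfect <- dplyr::mutate(truth, replicate = 1L)
  ev2 <- evaluate_dataset(perfect, truth, tolerances = c(0, 3))
  expect_true(all(ev2$replicates$f1 == 1))
  expect_true(all(ev2$summary$precision_sd == 0))
})

test_that("pooled 'all' precision lies within the per-class range", {
  set.seed(37)
  for (rep in 1:20) {
    counts <- tibble::tibble(
      replicate = 1L,
      class = c("Peptide", "Propeptide"),
      tp = sample(0:10, 2, replace = TRUE),
      fp = sample(0:10, 2, replace = TRUE),
      fn = sample(0:10, 2, replace = TRUE)
    )
    per <- precision_recall_f1(counts)
    pooled <- precision_recall_f1(tibble::tibble(
      tp = sum(counts$tp), fp = sum(counts$fp), fn = sum(counts$fn)))
    if (all(counts$tp + counts$fp > 0)) {
      expect_gte(pooled$precision, min(per$precision) - 1e-12)
      expect_lte(pooled$precision, max(per$precision) + 1e-12)
    }
  }
})
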