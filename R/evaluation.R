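#' Extract spans from per-position labels
#'
#' Two input forms are supported. An integer state path (with `space` given)
#' uses state boundaries: a span starts at every (c,1) state, so two
#' back-to-back same-class spans stay distinct. A character vector of merged
#' class labels uses maximal runs of each non-"None" class, which cannot
#' distinguish abutting spans — the form used for per-residue predictors.
#'
#' @param labels Integer state path or character class-label vector.
#' @param space Required for the state-path form.
#' @return Tibble with `start`, `end`, `class` (1-based inclusive).
#' @export
spans_from_labels <- function(labels, space = NULL) {
  if (is.numeric(labels)) {
    if (is.null(space)) stop("space is required for a state path")
    return(spans_from_state_path(as.integer(labels), space))
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "None"
  tibble::tibble(start = starts[keep], end = ends[keep], class = r$values[keep])
}

#' Group overlapping ground-truth spans
#'
#' Overlapping annotations of the same class form connected components under
#' interval overlap (transitively closed); each component is scored as a
#' single positive — a prediction matching any member counts.
#'
#' @param spans Tibble with `start`, `end` and optionally `class` (spans of
#'   different classes never share a group).
#' @return The input tibble with an integer `group` column added.
#' @export
collapse_overlap_groups <- function(spans) {
  if (!"class" %in% names(spans)) spans$class <- "all"
  if (nrow(spans) == 0L) {
    spans$group <- integer(0)
    return(spans)
  }
  ord <- order(spans$class, spans$start, spans$end)
  out <- spans[ord, , drop = FALSE]
  group <- integer(nrow(out))
  g <- 0L
  cur_class <- NA_character_
  cur_end <- -Inf
  for (k in seq_len(nrow(out))) {
    if (!identical(out$class[k], cur_class) || out$start[k] > cur_end) {
      g <- g + 1L
      cur_class <- out$class[k]
      cur_end <- out$end[k]
    } else {
      cur_end <- max(cur_end, out$end[k])
    }
    group[k] <- g
  }
  out$group <- group
  out[order(ord), , drop = FALSE]  # restore the caller's row order
}

#' Match predicted spans to truth groups within a tolerance window
#'
#' A prediction matches a truth group if for some member span both
#' `|pred_start - true_start| <= tolerance` and
#' `|pred_end - true_end| <= tolerance`. Matching is greedy one-to-one in
#' prediction order with ties to the earliest-starting group: each group
#' satisfied by at least one prediction counts one TP, predictions matching
#' no (still unmatched) group are FPs — including duplicates onto an
#' already-matched group — and unmatched groups are FNs. Spans are assumed to
#' belong to one sequence and one class (or to be compared class-agnostically).
#'
#' @param pred Tibble of predicted spans (`start`, `end`).
#' @param truth Tibble of true spans (`start`, `end`); overlap groups are
#'   formed internally.
#' @param tolerance Non-negative integer tolerance in residues.
#' @return Tibble with `tp`, `fp`, `fn`, `tolerance`.
#' @export
match_spans <- function(pred, truth, tolerance) {
  tolerance <- as.integer(tolerance)
  if (is.na(tolerance) || tolerance < 0L) stop("tolerance must be >= 0")
  truth <- truth[, c("start", "end"), drop = FALSE]
  grouped <- collapse_overlap_groups(truth)
  n_groups <- if (nrow(grouped)) max(grouped$group) else 0L
  group_start <- if (n_groups)
    vapply(seq_len(n_groups),
           function(g) min(grouped$start[grouped$group == g]), numeric(1))
  else numeric(0)
  matched <- logical(n_groups)
  tp <- 0L; fp <- 0L
  for (k in seq_len(nrow(pred))) {
    ok <- abs(pred$start[k] - grouped$start) <= tolerance &
      abs(pred$end[k] - grouped$end) <= tolerance
    cand <- setdiff(unique(grouped$group[ok]), which(matched))
    if (length(cand) == 0L) {
      fp <- fp + 1L
    } else {
      best <- cand[order(group_start[cand])][1L]
      matched[best] <- TRUE
      tp <- tp + 1L
    }
  }
  tibble::tibble(tp = tp, fp = fp, fn = n_groups - tp, tolerance = tolerance)
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1` their harmonic mean;
#' any zero denominator yields 0 by convention. Vectorised over rows, so a
#' whole counts table can be piped through.
#'
#' @param counts Tibble with `tp`, `fp`, `fn` (other columns pass through).
#' @return The input tibble with `precision`, `recall`, `f1` columns added.
#' @export
precision_recall_f1 <- function(counts) {
  p_den <- counts$tp + counts$fp
  r_den <- counts$tp + counts$fn
  precision <- ifelse(p_den > 0, counts$tp / p_den, 0)
  recall <- ifelse(r_den > 0, counts$tp / r_den, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  dplyr::mutate(counts, precision = precision, recall = recall, f1 = f1)
}

#' Contiguous segments above a probability threshold
#'
#' Converts a per-residue probability profile into spans: maximal runs of
#' positions with probability >= `threshold` (inclusive). This is the
#' comparator used to score per-residue predictors under the same span-level
#' matching protocol; 0.5 is the documented default.
#'
#' @param probs Numeric vector of per-position probabilities in \[0, 1\].
#' @param threshold Threshold in (0, 1); default 0.5.
#' @return Tibble with `start`, `end` (1-based inclusive).
#' @export
segments_from_probabilities <- function(probs, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  r <- rle(probs >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Span-level metrics over a dataset, per class, tolerance and replicate
#'
#' Counts are pooled over sequences (micro-averaged) within each replicate,
#' then precision/recall/F1 are computed per (replicate, class, tolerance);
#' the pooled class `"all"` sums peptide and propeptide counts before the
#' ratio. The summary reports mean and population standard deviation
#' (n = replicates) per cell. Sequences present in the truth but absent from
#' a replicate's predictions count as all-FN, with a warning.
#'
#' @param predictions Tibble with `replicate`, `id`, `start`, `end`, `class`.
#'   A `replicate` column is added (single replicate 1) if missing.
#' @param truth Tibble with `id`, `start`, `end`, `class`.
#' @param tolerances Integer vector of tolerance windows (default 0:3).
#' @param classes Span classes to score (default Peptide and Propeptide).
#' @return An object of class `peptide_eval`: list with `replicates` (tibble
#'   of per-replicate counts and metrics) and `summary` (tibble of mean/SD per
#'   class and tolerance).
#' @export
evaluate_dataset <- function(predictions, truth, tolerances = 0:3,
                             classes = c("Peptide", "Propeptide")) {
  if (!"replicate" %in% names(predictions)) predictions$replicate <- 1L
  replicates <- sort(unique(predictions$replicate))
  if (length(replicates) == 0L) replicates <- 1L
  truth <- truth[truth$class %in% classes, , drop = FALSE]
  ids <- unique(truth$id)

  missing_any <- FALSE
  rows <- list()
  for (rep_ in replicates) {
    pr <- predictions[predictions$replicate == rep_, , drop = FALSE]
    absent <- setdiff(ids, unique(pr$id))
    if (length(absent) > 0L &&
        any(truth$id %in% absent)) missing_any <- TRUE
    for (tol in tolerances) {
      per_class <- list()
      for (cl in classes) {
        tp <- 0L; fp <- 0L; fn <- 0L
        all_ids <- union(ids, unique(pr$id))
        for (id in all_ids) {
          p <- pr[pr$id == id & pr$class == cl, , drop = FALSE]
          t_ <- truth[truth$id == id & truth$class == cl, , drop = FALSE]
          if (nrow(p) == 0L && nrow(t_) == 0L) next
          m <- match_spans(p, t_, tol)
          tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
        }
        per_class[[cl]] <- tibble::tibble(replicate = rep_, class = cl,
                                          tolerance = tol, tp = tp, fp = fp,
                                          fn = fn)
      }
      pooled <- dplyr::bind_rows(per_class)
      rows[[length(rows) + 1L]] <- pooled
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = rep_, class = "all", tolerance = tol,
        tp = sum(pooled$tp), fp = sum(pooled$fp), fn = sum(pooled$fn)
      )
    }
  }
  if (missing_any)
    warning("some sequences in the truth have no predictions in at least ",
            "one replicate; they count as false negatives", call. = FALSE)

  per_rep <- precision_recall_f1(dplyr::bind_rows(rows))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary <- per_rep |>
    dplyr::group_by(.data$class, .data$tolerance) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(c("precision", "recall", "f1"),
                    list(mean = mean, sd = pop_sd)),
      .groups = "drop"
    )
  structure(list(replicates = per_rep, summary = summary),
            class = "peptide_eval")
}

#' @export
print.peptide_eval <- function(x, ...) {
  cat("<peptide_eval> ", length(unique(x$replicates$replicate)),
      " replicate(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write the per-replicate metrics table to TSV
#'
#' Columns: replicate, class, tolerance, tp, fp, fn, precision, recall, f1.
#'
#' @param x A `peptide_eval` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  stopifnot(inherits(x, "peptide_eval"))
  readr::write_tsv(x$replicates, path)
  invisible(path)
}

#' Plot precision/recall against the tolerance window
#'
#' @param object A `peptide_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peptide_eval
#' @export
autoplot.peptide_eval <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("precision_mean", "recall_mean"),
                        names_to = "metric", values_to = "mean") |>
    dplyr::mutate(
      sd = ifelse(.data$metric == "precision_mean",
                  .data$precision_sd, .data$recall_sd),
      metric = sub("_mean$", "", .data$metric)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tolerance, y = .data$mean,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                          ymax = pmin(1, .data$mean + .data$sd))) +
    ggplot2::facet_wrap(~class) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "tolerance window (residues)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
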