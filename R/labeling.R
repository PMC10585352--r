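#' Resolve overlapping annotations into a conflict-free subset
#'
#' Training labels need one state per position, so overlapping span
#' annotations cannot all be used at once. Each call uniformly shuffles the
#' annotation order and greedily accepts every annotation that does not
#' overlap an already accepted one (per sequence id), yielding a maximal
#' non-overlapping subset; annotations that overlap nothing are therefore
#' always retained. Called once per training epoch so that which annotation
#' wins a conflict varies across epochs.
#'
#' @param annotations Tibble with `id`, `start`, `end`, `class` (restricted to
#'   span classes, not Signal/Transit).
#' @param seed Optional integer; when given the shuffle is performed under
#'   this seed without disturbing the session RNG.
#' @return Tibble, a subset of the input rows (original order not preserved).
#' @export
sample_nonoverlapping <- function(annotations, seed = NULL) {
  run <- function() {
    if (nrow(annotations) <= 1L) return(annotations)
    shuffled <- annotations[sample.int(nrow(annotations)), , drop = FALSE]
    keep <- logical(nrow(shuffled))
    for (id in unique(shuffled$id)) {
      rows <- which(shuffled$id == id)
      acc_start <- integer(0)
      acc_end <- integer(0)
      for (r in rows) {
        s <- shuffled$start[r]; e <- shuffled$end[r]
        if (!any(s <= acc_end & e >= acc_start)) {
          keep[r] <- TRUE
          acc_start <- c(acc_start, s)
          acc_end <- c(acc_end, e)
        }
      }
    }
    shuffled[keep, , drop = FALSE]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Per-position state labels from span annotations
#'
#' Positions inside a span of class c get the states (c,1)...(c,L) in order;
#' all other positions get the background state. The annotations must already
#' be non-overlapping (see [sample_nonoverlapping()]) and length-filtered to
#' the state space's `[min_len, max_len]` range.
#'
#' @param sequence_length Integer T.
#' @param annotations Tibble with `start`, `end`, `class` for one sequence.
#' @param space A [build_state_space()] object.
#' @return Integer state vector of length T forming a valid path.
#' @export
labels_from_spans <- function(sequence_length, annotations, space) {
  stopifnot(inherits(space, "state_space"))
  T_ <- as.integer(sequence_length)
  if (T_ < 1L) stop("sequence length must be at least 1")
  states <- rep(1L, T_)
  if (nrow(annotations) > 0L) {
    ann <- annotations[order(annotations$start), , drop = FALSE]
    if (any(ann$end > T_ | ann$start < 1L))
      stop("annotation outside the sequence")
    len <- ann$end - ann$start + 1L
    if (any(len < space$min_len | len > space$max_len))
      stop("annotation length outside [", space$min_len, ", ", space$max_len,
           "]; apply filter_length() first")
    if (nrow(ann) > 1L && any(ann$start[-1L] <= ann$end[-nrow(ann)]))
      stop("annotations overlap; apply sample_nonoverlapping() first")
    for (k in seq_len(nrow(ann))) {
      ci <- match(ann$class[k], space$classes)
      if (is.na(ci)) stop("unknown span class: ", ann$class[k])
      first <- 2L + (ci - 1L) * space$max_len  # state (c, 1)
      states[ann$start[k]:ann$end[k]] <- first + seq_len(len[k]) - 1L
    }
  }
  if (!is_valid_path(states, space))
    stop("annotations produce an invalid label path (e.g. adjacent ",
         "cross-class spans or a span cut off at a boundary)")
  states
}

# Internal: deterministic per-(seed, epoch, id) sub-seed, < 2^31.
epoch_record_seed <- function(seed, epoch, id) {
  h <- sum(utf8ToInt(id) * seq_len(nchar(id))) %% 1000003L
  (as.integer(seed) * 7919L + as.integer(epoch) * 104729L + h) %% 2147483647L
}
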