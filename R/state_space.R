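#' Build the length-constrained CRF state space
#'
#' Constructs the state layout used by the span-labeling CRF: one background
#' ("None") state plus `max_len` position states per span class. A span of
#' class c is represented by the state run (c,1), (c,2), ..., (c,L); the
#' allowed-transition mask enforces that every decoded span has length between
#' `min_len` and `max_len` and that no path ever steps directly from one span
#' class into another. With the default configuration (lengths 5-50, classes
#' Peptide and Propeptide) the space has 1 + 2*50 = 101 states.
#'
#' Allowed transitions are exactly:
#' \itemize{
#'   \item None -> None and None -> (c,1) for each class c;
#'   \item (c,p) -> (c,p+1) for p < `max_len` (span continuation);
#'   \item (c,p) -> None and (c,p) -> (c,1) for p >= `min_len` (span end,
#'     optionally followed immediately by a new same-class span — tandem
#'     repeats of cleaved peptides occur in real precursors).
#' }
#' Cross-class adjacency is forbidden in both directions. Paths may start
#' inside a span (state (c,1)) and end inside one provided at least `min_len`
#' positions have been emitted; both behaviours can be switched off.
#'
#' @param min_len Minimum span length in residues (default 5).
#' @param max_len Maximum span length in residues (default 50).
#' @param classes Character vector of span class names (default
#'   `c("Peptide", "Propeptide")`). `"None"` is reserved for the background.
#' @param allow_same_class_adjacency If `TRUE` (default) a finished span may be
#'   followed immediately by a new span of the same class.
#' @param allow_boundary_spans If `TRUE` (default) spans may abut the sequence
#'   termini (e.g. an N-terminal peptide left after signal-peptide removal).
#' @return An object of class `state_space`: a list with `n_states`,
#'   `class_of_state`, `position_of_state`, `allowed_transition` (logical
#'   matrix), `allowed_initial`, `allowed_final`, `min_len`, `max_len`,
#'   `classes`.
#' @examples
#' sp <- build_state_space(5, 50, c("Peptide", "Propeptide"))
#' sp$n_states  # 101
#' @export
build_state_space <- function(min_len = 5L, max_len = 50L,
                              classes = c("Peptide", "Propeptide"),
                              allow_same_class_adjacency = TRUE,
                              allow_boundary_spans = TRUE) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (length(classes) < 1L) stop("at least one span class is required")
  if (anyDuplicated(classes)) stop("span classes must be unique")
  if ("None" %in% classes) stop("'None' is reserved for the background state")
  if (is.na(min_len) || is.na(max_len) || min_len < 1L)
    stop("min_len must be a positive integer")
  if (min_len > max_len) stop("min_len must not exceed max_len")

  n_cls <- length(classes)
  n_states <- 1L + n_cls * max_len
  class_of_state <- c("None", rep(classes, each = max_len))
  position_of_state <- c(0L, rep(seq_len(max_len), times = n_cls))

  idx <- function(ci, p) 1L + (ci - 1L) * max_len + p

  allowed <- matrix(FALSE, n_states, n_states)
  allowed[1L, 1L] <- TRUE
  for (ci in seq_len(n_cls)) {
    first <- idx(ci, 1L)
    allowed[1L, first] <- TRUE
    if (max_len > 1L)
      for (p in seq_len(max_len - 1L)) allowed[idx(ci, p), idx(ci, p + 1L)] <- TRUE
    for (p in min_len:max_len) {
      allowed[idx(ci, p), 1L] <- TRUE
      if (allow_same_class_adjacency) allowed[idx(ci, p), first] <- TRUE
    }
  }

  allowed_initial <- rep(FALSE, n_states)
  allowed_initial[1L] <- TRUE
  allowed_final <- rep(FALSE, n_states)
  allowed_final[1L] <- TRUE
  if (allow_boundary_spans) {
    for (ci in seq_len(n_cls)) {
      allowed_initial[idx(ci, 1L)] <- TRUE
      allowed_final[idx(ci, min_len:max_len)] <- TRUE
    }
  }

  structure(
    list(
      n_states = n_states,
      class_of_state = class_of_state,
      position_of_state = position_of_state,
      allowed_transition = allowed,
      allowed_initial = allowed_initial,
      allowed_final = allowed_final,
      min_len = min_len,
      max_len = max_len,
      classes = classes,
      allow_same_class_adjacency = allow_same_class_adjacency,
      allow_boundary_spans = allow_boundary_spans
    ),
    class = "state_space"
  )
}

#' Index of the state representing position `p` of class `class`
#'
#' Position 0 with class "None" addresses the background state.
#'
#' @param space A `state_space`.
#' @param class Class name ("None" or one of `space$classes`).
#' @param position Within-span position (ignored for "None").
#' @return Integer state index (1-based).
#' @export
state_index <- function(space, class, position = 0L) {
  stopifnot(inherits(space, "state_space"))
  if (class == "None") return(1L)
  ci <- match(class, space$classes)
  if (is.na(ci)) stop("unknown class: ", class)
  position <- as.integer(position)
  if (position < 1L || position > space$max_len)
    stop("position out of range for class ", class)
  1L + (ci - 1L) * space$max_len + position
}

#' Additive transition mask
#'
#' Returns the n_states x n_states matrix with 0 on allowed transitions and
#' -Inf elsewhere. Added to a transition weight matrix it blocks all forbidden
#' paths in every dynamic program (forward, backward, Viterbi).
#'
#' @param space A `state_space`.
#' @return Numeric matrix.
#' @export
transition_mask <- function(space) {
  stopifnot(inherits(space, "state_space"))
  ifelse(space$allowed_transition, 0, -Inf)
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", x$n_states, " states: None + ",
      paste(x$classes, collapse = "/"),
      " x positions 1..", x$max_len,
      "; span length in [", x$min_len, ", ", x$max_len, "]\n", sep = "")
  cat("  allowed transitions: ", sum(x$allowed_transition), "\n", sep = "")
  invisible(x)
}

# Internal: TRUE if the integer state sequence is a valid path under the masks.
is_valid_path <- function(states, space) {
  if (length(states) == 0L) return(FALSE)
  if (!space$allowed_initial[states[1L]]) return(FALSE)
  if (!space$allowed_final[states[length(states)]]) return(FALSE)
  if (length(states) > 1L) {
    from <- states[-length(states)]
    to <- states[-1L]
    if (!all(space$allowed_transition[cbind(from, to)])) return(FALSE)
  }
  TRUE
}
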