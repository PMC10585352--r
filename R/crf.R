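#' CRF parameters over a masked state space
#'
#' Bundles learnable transition weights with the state space they score.
#' Weights on forbidden transitions are never used: scoring always adds the
#' -Inf mask from [transition_mask()], so forbidden entries stay impossible
#' whatever their stored value.
#'
#' @param space A [build_state_space()] object.
#' @param transition_weights Optional numeric n_states x n_states matrix;
#'   defaults to all zeros (the training initialisation).
#' @return An object of class `crf_parameters`.
#' @export
crf_parameters <- function(space, transition_weights = NULL) {
  stopifnot(inherits(space, "state_space"))
  S <- space$n_states
  if (is.null(transition_weights)) {
    transition_weights <- matrix(0, S, S)
  }
  if (!is.matrix(transition_weights) || any(dim(transition_weights) != S))
    stop("transition_weights must be a ", S, " x ", S, " matrix")
  if (any(!is.finite(transition_weights[space$allowed_transition])))
    stop("transition weights on allowed transitions must be finite")
  structure(list(space = space, transition_weights = transition_weights),
            class = "crf_parameters")
}

# Internal: masked transition scores (weights where allowed, -Inf elsewhere).
masked_transitions <- function(params) {
  ifelse(params$space$allowed_transition, params$transition_weights, -Inf)
}

# Internal: additive initial/final masks as numeric vectors.
initial_mask <- function(space) ifelse(space$allowed_initial, 0, -Inf)
final_mask <- function(space) ifelse(space$allowed_final, 0, -Inf)

# Internal: column index into the T x K class-tied emission matrix per state.
state_class_index <- function(space) {
  match(space$class_of_state, c("None", space$classes))
}

#' Expand class-tied emissions to per-state scores
#'
#' The CRF computes one emission logit per class (None plus each span class)
#' per position and shares it among all states of that class, so the per-state
#' emission matrix simply repeats class columns.
#'
#' @param emissions Numeric T x K matrix, K = number of classes + 1, columns
#'   ordered (None, then `space$classes`).
#' @param space A `state_space`.
#' @return Numeric T x n_states matrix.
#' @export
expand_emissions <- function(emissions, space) {
  stopifnot(inherits(space, "state_space"))
  emissions <- as.matrix(emissions)
  K <- length(space$classes) + 1L
  if (ncol(emissions) != K)
    stop("emissions must have ", K, " columns (None + each span class)")
  if (any(!is.finite(emissions))) stop("emissions must be finite")
  emissions[, state_class_index(space), drop = FALSE]
}

# Internal: validate emissions + params, return expanded pieces for the DPs.
# The allowed-transition structure is sparse, so transitions are handed to the
# C++ recursions as an edge list (0-based from/to plus weight), ordered by
# target then source so Viterbi tie-breaking is deterministic.
crf_inputs <- function(emissions, params) {
  stopifnot(inherits(params, "crf_parameters"))
  emissions <- as.matrix(emissions)
  if (nrow(emissions) < 1L) stop("sequence length must be at least 1")
  space <- params$space
  edges <- which(space$allowed_transition, arr.ind = TRUE)  # column-major:
  # sorted by target state, then source ascending
  list(
    space = space,
    emis = expand_emissions(emissions, space),
    from0 = edges[, 1L] - 1L,
    to0 = edges[, 2L] - 1L,
    w = params$transition_weights[edges],
    init = initial_mask(space),
    fin = final_mask(space)
  )
}

#' Log-partition function of the CRF
#'
#' Log-sum-exp over all state paths that respect the allowed-initial,
#' allowed-final and allowed-transition masks, of the summed tied emission and
#' transition scores. Computed in log space by the forward algorithm.
#'
#' @param emissions Numeric T x K class-tied emission matrix.
#' @param params A [crf_parameters()] object.
#' @return Scalar log Z.
#' @export
forward_log_partition <- function(emissions, params) {
  inp <- crf_inputs(emissions, params)
  cpp_crf_forward(inp$emis, inp$from0, inp$to0, inp$w, inp$init, inp$fin)$logZ
}

# Internal: unnormalized log score of a given state path.
path_score <- function(inp, states) {
  T_ <- length(states)
  s <- inp$init[states[1L]] + inp$fin[states[T_]] +
    sum(inp$emis[cbind(seq_len(T_), states)])
  if (T_ > 1L) {
    trans <- inp$space$allowed_transition * 0
    trans[cbind(inp$from0 + 1L, inp$to0 + 1L)] <- inp$w
    s <- s + sum(trans[cbind(states[-T_], states[-1L])])
  }
  s
}

#' Negative log-likelihood of a label path
#'
#' `log Z - score(y)` where the path score sums the tied emission of each
#' position's state class and the transition weights along the path. The label
#' path must be valid under the transition mask; label generation from
#' filtered annotations can never produce an invalid path, so an invalid one
#' is an error rather than +Inf.
#'
#' @param emissions Numeric T x K class-tied emission matrix.
#' @param params A [crf_parameters()] object.
#' @param states Integer state path of length T (1-based state indices).
#' @return Scalar NLL (>= 0 up to numerical noise).
#' @export
nll_loss <- function(emissions, params, states) {
  inp <- crf_inputs(emissions, params)
  states <- as.integer(states)
  if (length(states) != nrow(inp$emis))
    stop("label path length must equal the sequence length")
  if (!is_valid_path(states, inp$space))
    stop("label path violates the transition mask")
  fwd <- cpp_crf_forward(inp$emis, inp$from0, inp$to0, inp$w, inp$init, inp$fin)
  fwd$logZ - path_score(inp, states)
}

#' Gradient of the NLL with respect to emissions and transition weights
#'
#' Standard exponential-family identities: the emission gradient at
#' (t, class) is the posterior probability mass of that class at t minus the
#' indicator of the observed class; the transition gradient is the expected
#' transition count minus the observed count, restricted to allowed entries.
#'
#' @inheritParams nll_loss
#' @return List with `emissions` (T x K) and `transitions` (n_states squared),
#'   plus the scalar `nll`.
#' @export
nll_gradient <- function(emissions, params, states) {
  inp <- crf_inputs(emissions, params)
  space <- inp$space
  states <- as.integer(states)
  T_ <- nrow(inp$emis)
  if (length(states) != T_)
    stop("label path length must equal the sequence length")
  if (!is_valid_path(states, space))
    stop("label path violates the transition mask")

  fwd <- cpp_crf_forward(inp$emis, inp$from0, inp$to0, inp$w, inp$init, inp$fin)
  beta <- cpp_crf_backward(inp$emis, inp$from0, inp$to0, inp$w, inp$fin)
  logZ <- fwd$logZ
  if (!is.finite(logZ)) stop("no valid path has finite score")

  m <- fwd$alpha + beta - logZ
  post <- exp(m)            # T x S state posteriors; exp(-Inf) = 0
  cls_idx <- state_class_index(space)
  K <- length(space$classes) + 1L
  # sum state posteriors within each class column
  tie <- matrix(0, space$n_states, K)
  tie[cbind(seq_len(space$n_states), cls_idx)] <- 1
  d_emis <- post %*% tie
  obs <- matrix(0, T_, K)
  obs[cbind(seq_len(T_), cls_idx[states])] <- 1
  d_emis <- d_emis - obs

  E <- cpp_crf_pairwise(fwd$alpha, beta, inp$emis, inp$from0, inp$to0, inp$w,
                        logZ)
  if (T_ > 1L) {
    from <- states[-T_]
    to <- states[-1L]
    obs_trans <- matrix(0, space$n_states, space$n_states)
    for (k in seq_along(from))
      obs_trans[from[k], to[k]] <- obs_trans[from[k], to[k]] + 1
    d_trans <- E - obs_trans
  } else {
    d_trans <- E
  }
  d_trans[!space$allowed_transition] <- 0

  nll <- logZ - path_score(inp, states)
  list(emissions = d_emis, transitions = d_trans, nll = nll)
}

#' Viterbi decoding
#'
#' Returns the highest-scoring valid state path; ties are broken toward the
#' lowest state index at every backtracking step so the output is
#' deterministic. Spans are reconstructed from state-path boundaries: a span
#' starts at each (c,1) state and ends where the position counter resets or
#' the path leaves the class branch.
#'
#' @inheritParams forward_log_partition
#' @return An object of class `path_decoding`: list with `state_path`
#'   (integer), `class_labels` (character, states merged per class), `spans`
#'   (tibble with `start`, `end`, `class`, 1-based inclusive), and `score`.
#' @export
viterbi_decode <- function(emissions, params) {
  inp <- crf_inputs(emissions, params)
  vit <- cpp_crf_viterbi(inp$emis, inp$from0, inp$to0, inp$w, inp$init,
                         inp$fin)
  path <- as.integer(vit$path)
  space <- inp$space
  structure(
    list(
      state_path = path,
      class_labels = space$class_of_state[path],
      spans = spans_from_state_path(path, space),
      score = vit$score
    ),
    class = "path_decoding"
  )
}

#' @export
print.path_decoding <- function(x, ...) {
  cat("<path_decoding> T = ", length(x$state_path),
      ", score = ", format(x$score), ", ", nrow(x$spans), " span(s)\n", sep = "")
  print(x$spans)
  invisible(x)
}

# Internal: spans from a state path using position resets as boundaries.
spans_from_state_path <- function(path, space) {
  cls <- space$class_of_state[path]
  pos <- space$position_of_state[path]
  starts <- integer(0)
  ends <- integer(0)
  classes <- character(0)
  open <- NA_integer_
  for (t in seq_along(path)) {
    in_span <- cls[t] != "None"
    if (in_span && pos[t] == 1L) {
      if (!is.na(open)) {  # previous span ended at t-1 (same-class adjacency)
        starts <- c(starts, open); ends <- c(ends, t - 1L)
        classes <- c(classes, cls[open])
      }
      open <- t
    } else if (!in_span && !is.na(open)) {
      starts <- c(starts, open); ends <- c(ends, t - 1L)
      classes <- c(classes, cls[open])
      open <- NA_integer_
    }
  }
  if (!is.na(open)) {
    starts <- c(starts, open); ends <- c(ends, length(path))
    classes <- c(classes, cls[open])
  }
  tibble::tibble(start = starts, end = ends, class = classes)
}

#' Posterior class marginals by forward-backward
#'
#' Per-position posterior state probabilities, summed within each class branch
#' so the profile has one column per class (None, then each span class). Rows
#' lie on the probability simplex.
#'
#' @inheritParams forward_log_partition
#' @return A T x K matrix of class `marginal_profile` with column names
#'   `c("None", space$classes)`.
#' @export
posterior_marginals <- function(emissions, params) {
  inp <- crf_inputs(emissions, params)
  space <- inp$space
  fwd <- cpp_crf_forward(inp$emis, inp$from0, inp$to0, inp$w, inp$init,
                         inp$fin)
  if (!is.finite(fwd$logZ)) stop("no valid path has finite score")
  beta <- cpp_crf_backward(inp$emis, inp$from0, inp$to0, inp$w, inp$fin)
  post <- exp(fwd$alpha + beta - fwd$logZ)
  cls_idx <- state_class_index(space)
  K <- length(space$classes) + 1L
  tie <- matrix(0, space$n_states, K)
  tie[cbind(seq_len(space$n_states), cls_idx)] <- 1
  out <- post %*% tie
  colnames(out) <- c("None", space$classes)
  class(out) <- c("marginal_profile", class(out))
  out
}

#' Plot a marginal profile
#'
#' Line plot of the per-position class posteriors, the standard way to inspect
#' a single precursor's prediction.
#'
#' @param object A `marginal_profile` from [posterior_marginals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marginal_profile
#' @export
autoplot.marginal_profile <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object)) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    tidyr::pivot_longer(-"position", names_to = "class", values_to = "posterior")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$posterior,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue position", y = "posterior probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
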