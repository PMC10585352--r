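# Independent brute-force oracles used to validate the dynamic programs and
# the span matching. All work by explicit enumeration on small instances and
# never call the code paths they check.

# Enumerate all valid state paths of length T under the space's masks.
# Returns a list of integer vectors (1-based state indices).
enumerate_paths <- function(space, T_) {
  paths <- list()
  extend <- function(prefix) {
    t_ <- length(prefix)
    if (t_ == T_) {
      if (space$allowed_final[prefix[T_]])
        paths[[length(paths) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    nxt <- which(space$allowed_transition[prefix[t_], ])
    for (s in nxt) extend(c(prefix, s))
  }
  for (s in which(space$allowed_initial)) extend(s)
  paths
}

# Score of one path under tied emissions (T x K) and transition weights.
oracle_path_score <- function(path, emissions, space, weights) {
  cls_idx <- match(space$class_of_state, c("None", space$classes))
  s <- sum(emissions[cbind(seq_along(path), cls_idx[path])])
  if (length(path) > 1L)
    s <- s + sum(weights[cbind(path[-length(path)], path[-1L])])
  s
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Exact log-partition, best path, and per-position class posteriors by
# enumeration over all valid paths.
oracle_crf <- function(emissions, space, weights) {
  paths <- enumerate_paths(space, nrow(emissions))
  scores <- vapply(paths, oracle_path_score, numeric(1),
                   emissions = emissions, space = space, weights = weights)
  logZ <- log_sum_exp(scores)
  probs <- exp(scores - logZ)
  K <- length(space$classes) + 1L
  cls_idx <- match(space$class_of_state, c("None", space$classes))
  post <- matrix(0, nrow(emissions), K)
  for (p in seq_along(paths)) {
    path <- paths[[p]]
    for (t in seq_along(path))
      post[t, cls_idx[path[t]]] <- post[t, cls_idx[path[t]]] + probs[p]
  }
  best <- which.max(scores)
  list(logZ = logZ, paths = paths, scores = scores,
       viterbi_score = scores[best], posteriors = post)
}

# Maximum-TP bipartite matching between predictions and truth groups by
# exhaustive recursion (instances <= 8 spans).
oracle_max_matching <- function(pred, truth, tolerance) {
  grouped <- collapse_overlap_groups(truth[, c("start", "end"), drop = FALSE])
  n_groups <- if (nrow(grouped)) max(grouped$group) else 0L
  can <- matrix(FALSE, nrow(pred), n_groups)
  for (k in seq_len(nrow(pred))) {
    ok <- abs(pred$start[k] - grouped$start) <= tolerance &
      abs(pred$end[k] - grouped$end) <= tolerance
    can[k, unique(grouped$group[ok])] <- TRUE
  }
  best <- 0L
  recurse <- function(k, used) {
    if (k > nrow(pred)) {
      best <<- max(best, sum(used))
      return(invisible(NULL))
    }
    recurse(k + 1L, used)  # leave prediction k unmatched
    for (g in which(can[k, ] & !used)) {
      used[g] <- TRUE
      recurse(k + 1L, used)
      used[g] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, n_groups))
  tp <- best
  list(tp = tp, fp = nrow(pred) - tp, fn = n_groups - tp)
}

# Numeric gradient by central differences.
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
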