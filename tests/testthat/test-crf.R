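# Core CRF dynamic programs, checked against explicit path enumeration on
# small state spaces and against closed-form degenerate cases.

small_space <- function() build_state_space(2, 3, "Peptide")

random_params <- function(space, sd = 0.5) {
  w <- matrix(0, space$n_states, space$n_states)
  w[space$allowed_transition] <- rnorm(sum(space$allowed_transition), sd = sd)
  crf_parameters(space, w)
}

test_that("emission tying expands one score per class to all its states", {
  sp <- build_state_space(5, 50, c("Peptide", "Propeptide"))
  e <- matrix(c(1.5, -2, 0.25), 1, 3)
  ex <- expand_emissions(e, sp)
  expect_equal(dim(ex), c(1L, 101L))
  expect_equal(sum(ex == 1.5), 1)
  expect_equal(sum(ex == -2), 50)
  expect_equal(sum(ex == 0.25), 50)
  # perturbing the Peptide logit changes exactly the 50 peptide columns
  e2 <- e; e2[2] <- 7
  expect_equal(sum(expand_emissions(e2, sp) != ex), 50)
  expect_equal(unname(expand_emissions(matrix(0, 4, 3), sp)),
               matrix(0, 4, 101))
})

test_that("log-partition matches path enumeration on random small instances", {
  sp <- small_space()
  set.seed(42)
  for (rep in 1:30) {
    T_ <- sample(1:6, 1)
    e <- matrix(rnorm(T_ * 2), T_, 2)
    params <- random_params(sp)
    orc <- oracle_crf(e, sp, params$transition_weights)
    expect_equal(forward_log_partition(e, params), orc$logZ, tolerance = 1e-8)
  }
})

test_that("zero scores give log of the number of valid paths", {
  sp <- small_space()
  params <- crf_parameters(sp)
  for (T_ in 1:5) {
    e <- matrix(0, T_, 2)
    n_paths <- length(enumerate_paths(sp, T_))
    expect_equal(forward_log_partition(e, params), log(n_paths),
                 tolerance = 1e-10)
  }
})

test_that("a single position with min_len > 1 leaves only the background path", {
  sp <- build_state_space(2, 3, "Peptide")
  e <- matrix(c(0.7, 99), 1, 2)  # span emission is huge but unreachable
  expect_equal(forward_log_partition(e, crf_parameters(sp)), 0.7,
               tolerance = 1e-12)
})

test_that("NLL equals -log P(y) from the enumeration oracle and sums to one", {
  sp <- small_space()
  set.seed(7)
  for (rep in 1:10) {
    T_ <- sample(2:6, 1)
    e <- matrix(rnorm(T_ * 2), T_, 2)
    params <- random_params(sp)
    orc <- oracle_crf(e, sp, params$transition_weights)
    # every enumerated path: exp(-nll) must equal its normalized probability,
    # and the probabilities must sum to 1
    total <- 0
    for (p in seq_along(orc$paths)) {
      nll <- nll_loss(e, params, orc$paths[[p]])
      expect_gte(nll, -1e-10)
      expect_equal(exp(-nll), exp(orc$scores[p] - orc$logZ), tolerance = 1e-8)
      total <- total + exp(-nll)
    }
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("an invalid label path is an error", {
  sp <- small_space()
  e <- matrix(0, 3, 2)
  p1 <- state_index(sp, "Peptide", 1)
  expect_error(nll_loss(e, crf_parameters(sp), c(p1, 1L, 1L)),
               "transition mask")
})

test_that("Viterbi matches the enumeration oracle and reports its own score", {
  sp <- small_space()
  set.seed(13)
  for (rep in 1:30) {
    T_ <- sample(1:6, 1)
    e <- matrix(rnorm(T_ * 2), T_, 2)
    params <- random_params(sp)
    orc <- oracle_crf(e, sp, params$transition_weights)
    dec <- viterbi_decode(e, params)
    expect_equal(dec$score, orc$viterbi_score, tolerance = 1e-8)
    expect_equal(oracle_path_score(dec$state_path, e, sp,
                                   params$transition_weights),
                 dec$score, tolerance = 1e-8)
    expect_lte(dec$score, orc$logZ + 1e-10)
  }
})

test_that("sequences shorter than min_len decode to all background", {
  sp <- build_state_space(5, 50, c("Peptide", "Propeptide"))
  params <- crf_parameters(sp)
  e <- matrix(c(-10, 10, 10), 3, 3, byrow = TRUE)  # spans strongly favored
  dec <- viterbi_decode(e, params)
  expect_equal(dec$state_path, rep(1L, 3))
  expect_equal(nrow(dec$spans), 0L)
})

test_that("emissions peaked on a block decode to exactly that span", {
  sp <- build_state_space(5, 50, c("Peptide", "Propeptide"))
  e <- matrix(0, 30, 3)
  e[, 1] <- 4
  e[11:17, 1] <- -4   # positions 11..17 1-based
  e[11:17, 2] <- 4
  dec <- viterbi_decode(e, crf_parameters(sp))
  expect_equal(dec$spans,
               tibble::tibble(start = 11L, end = 17L, class = "Peptide"))
})

test_that("marginals match enumeration, rows sum to 1, and respect the mask", {
  sp <- small_space()
  set.seed(99)
  for (rep in 1:20) {
    T_ <- sample(1:6, 1)
    e <- matrix(rnorm(T_ * 2), T_, 2)
    params <- random_params(sp)
    orc <- oracle_crf(e, sp, params$transition_weights)
    m <- posterior_marginals(e, params)
    expect_equal(unname(unclass(m)), orc$posteriors, tolerance = 1e-8)
    expect_equal(rowSums(m), rep(1, T_), tolerance = 1e-6)
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
  }
  # no valid path visits span states when the sequence is too short
  sp2 <- build_state_space(5, 50, c("Peptide", "Propeptide"))
  m2 <- posterior_marginals(matrix(rnorm(9), 3, 3), crf_parameters(sp2))
  expect_equal(unname(m2[, "Peptide"]), rep(0, 3))
  expect_equal(unname(m2[, "Propeptide"]), rep(0, 3))
})

test_that("every decoded span respects the length bounds and class purity", {
  sp <- build_state_space(5, 50, c("Peptide", "Propeptide"))
  params <- crf_parameters(sp)
  set.seed(4)
  for (rep in 1:200) {
    e <- matrix(rnorm(40 * 3), 40, 3)
    dec <- viterbi_decode(e, params)
    if (nrow(dec$spans) > 0) {
      len <- dec$spans$end - dec$spans$start + 1
      expect_true(all(len >= 5 & len <= 50))
    }
    cls <- dec$class_labels
    adj <- cls[-1] != cls[-length(cls)] & cls[-1] != "None" &
      cls[-length(cls)] != "None"
    # class switches are only legal at a position-1 state of the same class,
    # so any direct peptide<->propeptide adjacency is a violation
    expect_false(any(adj))
  }
})

test_that("NLL gradients agree with finite differences", {
  sp <- small_space()
  set.seed(21)
  T_ <- 6
  e <- matrix(rnorm(T_ * 2), T_, 2)
  w <- matrix(0, sp$n_states, sp$n_states)
  w[sp$allowed_transition] <- rnorm(sum(sp$allowed_transition), sd = 0.3)
  y <- labels_from_spans(T_, tibble::tibble(start = 3L, end = 5L,
                                            class = "Peptide"), sp)

  g <- nll_gradient(e, crf_parameters(sp, w), y)
  expect_equal(g$nll, nll_loss(e, crf_parameters(sp, w), y), tolerance = 1e-10)

  ng_e <- numeric_grad(function(ev) {
    nll_loss(matrix(ev, T_, 2), crf_parameters(sp, w), y)
  }, as.numeric(e))
  expect_lt(max(abs(ng_e - as.numeric(g$emissions))) /
              max(1, max(abs(ng_e))), 1e-6)

  idx <- which(sp$allowed_transition)
  ng_w <- numeric_grad(function(wv) {
    w2 <- w; w2[idx] <- wv
    nll_loss(e, crf_parameters(sp, w2), y)
  }, w[idx])
  expect_lt(max(abs(ng_w - g$transitions[idx])) / max(1, max(abs(ng_w))), 1e-6)
})

test_that("scaling up emission logits never increases the Viterbi path loss", {
  # with no transition weights the Viterbi path maximizes the emission score,
  # so sharpening the emissions can only concentrate mass on it
  sp <- small_space()
  params <- crf_parameters(sp)
  set.seed(31)
  for (rep in 1:20) {
    e <- matrix(rnorm(6 * 2), 6, 2)
    y <- viterbi_decode(e, params)$state_path
    expect_lte(nll_loss(2 * e, params, y) - 1e-9,
               nll_loss(e, params, y))
  }
})

test_that("log-partition is stable for logits up to +/- 1e3", {
  sp <- build_state_space(5, 50, c("Peptide", "Propeptide"))
  e <- matrix(c(1e3, -1e3, -1e3), 20, 3, byrow = TRUE)
  lz <- forward_log_partition(e, crf_parameters(sp))
  expect_true(is.finite(lz))
  expect_equal(lz, 20 * 1e3, tolerance = 1e-6)  # all-background dominates
})
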