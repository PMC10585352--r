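# Adam optimizer over a named list of arrays. No installed package exposes a
# plain Adam step for arbitrary parameter lists, so it is implemented here.
adam_init <- function(params) {
  list(m = purrr::map(params, function(p) p * 0),
       v = purrr::map(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t_ <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / (1 - beta1^t_)
    v_hat <- state$v[[nm]] / (1 - beta2^t_)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(params = params, state = state)
}

# Internal: per-record input features for a given front-end.
record_features <- function(sequences, frontend, embeddings) {
  if (frontend == "onehot") {
    feats <- purrr::map(sequences$sequence, one_hot_encode)
  } else {
    feats <- embeddings[sequences$id]
    if (any(vapply(feats, is.null, logical(1))))
      stop("embeddings missing for some sequence ids")
    bad <- vapply(seq_len(nrow(sequences)), function(i) {
      nrow(feats[[i]]) != nchar(sequences$sequence[i])
    }, logical(1))
    if (any(bad))
      stop("embedding row count does not match sequence length for: ",
           paste(sequences$id[bad], collapse = ", "))
  }
  stats::setNames(feats, sequences$id)
}

#' Train the span-labeling CRF end to end
#'
#' Minimises the mean per-sequence negative log-likelihood by Adam gradient
#' steps on the emission-model parameters and the allowed transition weights
#' jointly (batch = one sequence; sequences are never padded — the dynamic
#' programs run per sequence). Overlapping span annotations are re-resolved
#' at every epoch with [sample_nonoverlapping()] under a per-(seed, epoch,
#' record) sub-seed, so conflicting annotations alternate across epochs while
#' runs stay reproducible. After each epoch the model is Viterbi-decoded on
#' the validation split and the mean of the per-class span F1 scores (at the
#' given tolerance window) is computed; the best-scoring checkpoint is kept
#' and training stops early once `patience` epochs pass without improvement.
#'
#' @param dataset A [peptide_dataset()] whose span annotations are already
#'   length-filtered to the state space's range.
#' @param train_ids,val_ids Disjoint sequence id sets.
#' @param space State space (default the 101-state peptide/propeptide layout).
#' @param frontend `"onehot"` or `"embeddings"`.
#' @param embeddings Named list of T x D matrices when
#'   `frontend = "embeddings"`.
#' @param architecture Emission architecture, see [emission_model()].
#' @param emission_config Named list overriding emission-model sizes
#'   (`channels`, `kernel`, `hidden`).
#' @param epochs Maximum epochs (default 50); must be >= 1.
#' @param patience Early-stopping patience in epochs (default 5).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param tolerance Tolerance window for the validation F1 metric (default 3).
#' @param seed Integer seed governing initialisation, epoch shuffles and
#'   overlap resampling.
#' @param verbose Print one line per epoch.
#' @return An object of class `peptide_crf`: the fitted model with its
#'   `history` tibble (epoch, mean train NLL, per-class and mean validation
#'   F1) and `best_epoch`.
#' @export
train_crf <- function(dataset, train_ids, val_ids,
                      space = build_state_space(),
                      frontend = c("onehot", "embeddings"),
                      embeddings = NULL,
                      architecture = c("conv", "cnn_lstm_cnn"),
                      emission_config = list(),
                      epochs = 50L, patience = 5L, learning_rate = 1e-3,
                      tolerance = 3L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(dataset, "peptide_dataset"),
            inherits(space, "state_space"))
  frontend <- match.arg(frontend)
  architecture <- match.arg(architecture)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be at least 1")
  if (length(train_ids) == 0L) stop("training set is empty")
  if (length(intersect(train_ids, val_ids)) > 0L)
    stop("train and validation ids must be disjoint")
  missing_ids <- setdiff(c(train_ids, val_ids), dataset$sequences$id)
  if (length(missing_ids) > 0L)
    stop("ids not in the dataset: ", paste(head(missing_ids, 5), collapse = ", "))

  seqs <- dataset$sequences
  ann <- dataset$annotations
  ann <- ann[ann$class %in% space$classes, , drop = FALSE]
  feats <- record_features(seqs[seqs$id %in% c(train_ids, val_ids), ,
                                drop = FALSE], frontend, embeddings)
  d_in <- ncol(feats[[1]])

  em_args <- c(list(architecture = architecture, d_in = d_in,
                    n_classes = length(space$classes) + 1L, seed = seed),
               emission_config)
  model <- do.call(emission_model, em_args)

  params <- c(model$params, list(trans = matrix(0, space$n_states,
                                                space$n_states)))
  opt <- adam_init(params)
  allowed <- space$allowed_transition

  val_f1 <- function(params) {
    em <- model; em$params <- params[names(model$params)]
    crf <- crf_parameters(space, params$trans)
    pred_rows <- purrr::map(val_ids, function(id) {
      e <- emission_forward(em, feats[[id]])$logits
      sp <- viterbi_decode(e, crf)$spans
      if (nrow(sp) > 0L) dplyr::mutate(sp, id = id) else NULL
    })
    preds <- dplyr::bind_rows(pred_rows)
    if (nrow(preds) == 0L)
      preds <- tibble::tibble(id = character(0), start = integer(0),
                              end = integer(0), class = character(0))
    truth <- ann[ann$id %in% val_ids, , drop = FALSE]
    f1s <- vapply(space$classes, function(cl) {
      tp <- 0L; fp <- 0L; fn <- 0L
      for (id in val_ids) {
        p <- preds[preds$id == id & preds$class == cl, , drop = FALSE]
        t_ <- truth[truth$id == id & truth$class == cl, , drop = FALSE]
        if (nrow(p) == 0L && nrow(t_) == 0L) next
        m <- match_spans(p, t_, tolerance)
        tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      }
      precision_recall_f1(tibble::tibble(tp = tp, fp = fp, fn = fn))$f1
    }, numeric(1))
    f1s
  }

  history <- list()
  best <- list(score = -Inf, params = params, epoch = 0L)
  epochs_since_best <- 0L

  for (epoch in seq_len(epochs)) {
    order_ids <- withr::with_seed(epoch_record_seed(seed, epoch, "epoch-order"),
                                  sample(train_ids))
    nlls <- numeric(length(order_ids))
    for (k in seq_along(order_ids)) {
      id <- order_ids[k]
      a <- ann[ann$id == id, , drop = FALSE]
      a <- sample_nonoverlapping(a, seed = epoch_record_seed(seed, epoch, id))
      T_ <- nchar(seqs$sequence[seqs$id == id])
      y <- labels_from_spans(T_, a, space)

      em <- model; em$params <- params[names(model$params)]
      fw <- emission_forward(em, feats[[id]])
      crf <- crf_parameters(space, params$trans)
      g <- nll_gradient(fw$logits, crf, y)
      em_grads <- emission_backward(em, feats[[id]], fw$cache, g$emissions)
      g$transitions[!allowed] <- 0
      grads <- c(em_grads, list(trans = g$transitions))
      if (learning_rate > 0) {
        upd <- adam_step(params, grads, opt, lr = learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      nlls[k] <- g$nll
    }

    f1s <- if (length(val_ids) > 0L) val_f1(params) else
      stats::setNames(rep(NA_real_, length(space$classes)), space$classes)
    mean_f1 <- mean(f1s)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_nll = mean(nlls),
      !!!stats::setNames(as.list(f1s), paste0("val_f1_", tolower(space$classes))),
      val_mean_f1 = mean_f1
    )
    if (verbose)
      message(sprintf("epoch %d: train NLL %.4f, val mean F1 %.4f",
                      epoch, mean(nlls), mean_f1))
    if (!is.na(mean_f1) && mean_f1 > best$score) {
      best <- list(score = mean_f1, params = params, epoch = epoch)
      epochs_since_best <- 0L
    } else {
      epochs_since_best <- epochs_since_best + 1L
      if (length(val_ids) > 0L && epochs_since_best >= patience) break
    }
  }

  final_params <- if (length(val_ids) > 0L && best$epoch > 0L) best$params
  else params
  model$params <- final_params[names(model$params)]
  structure(list(
    space = space,
    frontend = frontend,
    emission = model,
    transition_weights = final_params$trans,
    config = list(epochs = epochs, patience = patience,
                  learning_rate = learning_rate, tolerance = tolerance,
                  seed = seed, architecture = architecture),
    history = dplyr::bind_rows(history),
    best_epoch = if (best$epoch > 0L) best$epoch else NA_integer_,
    best_val_f1 = if (is.finite(best$score)) best$score else NA_real_,
    format = list(name = "peptidecrf-model", version = 1L)
  ), class = "peptide_crf")
}

#' @export
print.peptide_crf <- function(x, ...) {
  cat("<peptide_crf> ", x$emission$architecture, " emissions over ",
      x$frontend, " input; ", x$space$n_states, " states\n", sep = "")
  cat("  trained ", nrow(x$history), " epoch(s); best epoch ",
      x$best_epoch, " (val mean F1 ",
      format(x$best_val_f1, digits = 3), ")\n", sep = "")
  invisible(x)
}

# Internal: emissions for one record under a fitted model.
model_emissions <- function(model, sequence, id = NULL, embeddings = NULL) {
  x <- if (model$frontend == "onehot") one_hot_encode(sequence)
  else {
    if (is.null(embeddings) || is.null(embeddings[[id]]))
      stop("embeddings required for id: ", id)
    embeddings[[id]]
  }
  emission_forward(model$emission, x)$logits
}

#' Predict spans (and marginals) for new sequences
#'
#' Viterbi-decodes each sequence under the fitted model. Sequences shorter
#' than the minimum span length decode to the all-background path and yield
#' zero spans.
#'
#' @param object A fitted `peptide_crf`.
#' @param sequences Tibble with `id`, `sequence` (or a [peptide_dataset()]).
#' @param type `"spans"`, `"marginals"` or `"both"`.
#' @param embeddings Named list of embedding matrices when the model uses the
#'   embeddings front-end.
#' @param ... Unused.
#' @return For `"spans"`: tibble `id`, `start`, `end`, `class`. For
#'   `"marginals"`: named list of `marginal_profile` matrices. For `"both"`:
#'   list with both.
#' @export
predict.peptide_crf <- function(object, sequences, type = c("spans",
                                                            "marginals",
                                                            "both"),
                                embeddings = NULL, ...) {
  type <- match.arg(type)
  if (inherits(sequences, "peptide_dataset")) sequences <- sequences$sequences
  crf <- crf_parameters(object$space, object$transition_weights)
  spans <- list()
  marginals <- list()
  for (i in seq_len(nrow(sequences))) {
    id <- sequences$id[i]
    e <- model_emissions(object, sequences$sequence[i], id, embeddings)
    if (type %in% c("spans", "both")) {
      sp <- viterbi_decode(e, crf)$spans
      if (nrow(sp) > 0L) spans[[id]] <- dplyr::mutate(sp, id = id)
    }
    if (type %in% c("marginals", "both"))
      marginals[[id]] <- posterior_marginals(e, crf)
  }
  span_tbl <- if (length(spans)) {
    dplyr::relocate(dplyr::bind_rows(spans), "id")
  } else {
    tibble::tibble(id = character(0), start = integer(0), end = integer(0),
                   class = character(0))
  }
  switch(type,
         spans = span_tbl,
         marginals = marginals,
         both = list(spans = span_tbl, marginals = marginals))
}

#' Ensemble prediction over replicate models
#'
#' Decoding runs Viterbi on the element-wise mean of the per-model emission
#' matrices under a CRF whose transition weights are the element-wise mean of
#' the per-model weights (each allowed transition weight has the same
#' interpretable role in every replicate, which is what makes plain averaging
#' sound). Marginals are the arithmetic mean of the per-model
#' forward-backward profiles — not the marginals of the averaged model — so
#' the decoded path and the marginals may legitimately disagree.
#'
#' @param models List of fitted `peptide_crf` models sharing one state space
#'   and front-end.
#' @param sequences Tibble with `id`, `sequence` (or a [peptide_dataset()]).
#' @param embeddings Optional embeddings for the embeddings front-end.
#' @return List with `spans` (tibble `id`, `start`, `end`, `class`) and
#'   `marginals` (named list of averaged profiles).
#' @export
ensemble_predict <- function(models, sequences, embeddings = NULL) {
  if (length(models) == 0L) stop("model list is empty")
  if (!all(vapply(models, inherits, logical(1), "peptide_crf")))
    stop("all models must be peptide_crf objects")
  ref <- models[[1]]$space
  same <- vapply(models, function(m) {
    identical(m$space$n_states, ref$n_states) &&
      identical(m$space$classes, ref$classes) &&
      identical(m$space$min_len, ref$min_len) &&
      identical(m$space$max_len, ref$max_len)
  }, logical(1))
  if (!all(same)) stop("models use mismatched state spaces")
  if (inherits(sequences, "peptide_dataset")) sequences <- sequences$sequences

  trans_mean <- Reduce(`+`, lapply(models, function(m) m$transition_weights)) /
    length(models)
  crf <- crf_parameters(ref, trans_mean)

  spans <- list()
  marginals <- list()
  for (i in seq_len(nrow(sequences))) {
    id <- sequences$id[i]
    emis <- lapply(models, function(m)
      model_emissions(m, sequences$sequence[i], id, embeddings))
    e_mean <- Reduce(`+`, emis) / length(emis)
    sp <- viterbi_decode(e_mean, crf)$spans
    if (nrow(sp) > 0L) spans[[id]] <- dplyr::mutate(sp, id = id)
    margs <- purrr::map2(models, emis, function(m, e)
      unclass(posterior_marginals(e, crf_parameters(ref, m$transition_weights))))
    mavg <- Reduce(`+`, margs) / length(margs)
    class(mavg) <- c("marginal_profile", class(mavg))
    marginals[[id]] <- mavg
  }
  span_tbl <- if (length(spans)) dplyr::relocate(dplyr::bind_rows(spans), "id")
  else tibble::tibble(id = character(0), start = integer(0),
                      end = integer(0), class = character(0))
  list(spans = span_tbl, marginals = marginals)
}

#' Save / load a fitted model
#'
#' The checkpoint serialises the state-space configuration, emission-model
#' weights, transition matrix and training config under a format version.
#'
#' @param model A `peptide_crf`.
#' @param path Checkpoint path.
#' @return `path` invisibly / the restored `peptide_crf`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "peptide_crf"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "peptide_crf") ||
      !identical(model$format$name, "peptidecrf-model"))
    stop("not a peptidecrf model checkpoint: ", path)
  model
}

#' Tidy the learned transition weights
#'
#' One row per allowed transition with the originating and receiving state's
#' class and within-span position.
#'
#' @param x A fitted `peptide_crf`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy peptide_crf
#' @export
tidy.peptide_crf <- function(x, ...) {
  sp <- x$space
  idx <- which(sp$allowed_transition, arr.ind = TRUE)
  tibble::tibble(
    from_class = sp$class_of_state[idx[, 1]],
    from_position = sp$position_of_state[idx[, 1]],
    to_class = sp$class_of_state[idx[, 2]],
    to_position = sp$position_of_state[idx[, 2]],
    weight = x$transition_weights[idx]
  )
}

#' One-row model summary
#'
#' @param x A fitted `peptide_crf`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance peptide_crf
#' @export
glance.peptide_crf <- function(x, ...) {
  tibble::tibble(
    architecture = x$emission$architecture,
    frontend = x$frontend,
    n_states = x$space$n_states,
    n_parameters = sum(vapply(x$emission$params, length, integer(1))) +
      sum(x$space$allowed_transition),
    epochs_trained = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_mean_f1 = x$best_val_f1
  )
}

#' Plot the training history
#'
#' @param object A fitted `peptide_crf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peptide_crf
#' @export
autoplot.peptide_crf <- function(object, ...) {
  df <- object$history |>
    dplyr::select("epoch", "train_nll", "val_mean_f1") |>
    tidyr::pivot_longer(-"epoch", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}
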