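#' The 33-token residue vocabulary
#'
#' The fixed tokenizer ordering used for one-hot encoding: 4 leading special
#' tokens, the 25 residue letters (20 standard amino acids plus X/B/U/Z/O),
#' `.` and `-`, then two trailing special tokens — 33 tokens in total, pinned
#' so one-hot models are reproducible without any language model installed.
#' Sequences are encoded without BOS/EOS: one row per residue.
#'
#' @return Character vector of length 33.
#' @export
esm_vocab <- function() {
  c("<cls>", "<pad>", "<eos>", "<unk>",
    "L", "A", "G", "V", "S", "E", "R", "T", "I", "D", "P", "K", "Q", "N",
    "F", "Y", "M", "H", "W", "C", "X", "B", "U", "Z", "O", ".", "-",
    "<null_1>", "<mask>")
}

#' One-hot encode an amino-acid sequence
#'
#' Each residue becomes a length-33 indicator row over [esm_vocab()];
#' characters outside the vocabulary map to the `<unk>` token.
#'
#' @param sequence Amino-acid string.
#' @param vocab Ordered token vector (default [esm_vocab()]).
#' @return A T x length(vocab) matrix with one 1 per row; class
#'   `embedding_matrix`.
#' @export
one_hot_encode <- function(sequence, vocab = esm_vocab()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0L) stop("sequence must be non-empty")
  idx <- match(chars, vocab)
  idx[is.na(idx)] <- match("<unk>", vocab)
  m <- matrix(0, length(chars), length(vocab))
  m[cbind(seq_along(chars), idx)] <- 1
  colnames(m) <- vocab
  m
}

#' Write precomputed per-residue embeddings
#'
#' The container is a keyed-array store: one T x D numeric matrix per
#' sequence id, all with the same width D, serialized with a format/version
#' header. Values survive a write/read round trip bit-exactly.
#'
#' @param embeddings Named list of T x D matrices, names = sequence ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  if (is.null(names(embeddings)) || any(names(embeddings) == ""))
    stop("embeddings must be a named list keyed by sequence id")
  widths <- vapply(embeddings, ncol, integer(1))
  if (length(unique(widths)) > 1L)
    stop("all embedding matrices must share one width; found: ",
         paste(unique(widths), collapse = ", "))
  saveRDS(list(format = "peptidecrf-embeddings", version = 1L,
               data = embeddings), path)
  invisible(path)
}

#' Read precomputed per-residue embeddings
#'
#' @param path Path written by [write_embeddings()].
#' @param ids Optional ids to extract; an absent id is an error naming it.
#' @return Named list of T x D matrices.
#' @export
read_embeddings <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("embedding container not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "peptidecrf-embeddings"))
    stop("not a peptidecrf embedding container: ", path)
  data <- obj$data
  widths <- vapply(data, ncol, integer(1))
  if (length(unique(widths)) > 1L)
    stop("embedding container has inconsistent widths")
  if (is.null(ids)) return(data)
  missing <- setdiff(ids, names(data))
  if (length(missing) > 0L)
    stop("embedding container is missing id(s): ",
         paste(missing, collapse = ", "))
  data[ids]
}

# ---- neural emission models -------------------------------------------------
#
# Pluggable per-position feature extractors mapping a T x D input (one-hot or
# precomputed embeddings) to a T x 3 emission logit matrix. Two architectures:
#   "conv"          windowed linear -> ReLU -> position-wise linear
#   "cnn_lstm_cnn"  conv (ReLU) -> bidirectional LSTM -> conv to 3 logits
# Both implement forward and exact backward passes so the CRF can be trained
# end to end; gradients are verified against finite differences in the tests.

#' Construct an emission model
#'
#' @param architecture `"conv"` (default for one-hot input: a windowed linear
#'   layer sees the flanking residues directly) or `"cnn_lstm_cnn"` (the
#'   convolution-recurrent-convolution network; the recurrent layer carries
#'   long-range context).
#' @param d_in Input width (33 for one-hot, the embedding width otherwise).
#' @param channels Convolution width (default 64).
#' @param kernel Convolution kernel size, odd (default 3; the conv model
#'   defaults to 7 so its receptive field covers the 2-residue flanks with
#'   slack).
#' @param hidden Recurrent hidden size per direction (default 64);
#'   cnn_lstm_cnn only.
#' @param n_classes Number of emission classes (default 3).
#' @param seed Seed for the random weight initialisation.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(architecture = c("conv", "cnn_lstm_cnn"), d_in,
                           channels = 64L, kernel = NULL, hidden = 64L,
                           n_classes = 3L, seed = 1L) {
  architecture <- match.arg(architecture)
  if (is.null(kernel)) kernel <- if (architecture == "conv") 7L else 3L
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("kernel size must be odd")
  init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.1), nr, nc)
  params <- withr::with_seed(as.integer(seed), {
    if (architecture == "conv") {
      list(
        W1 = init(kernel * d_in, channels), b1 = rep(0, channels),
        W2 = init(channels, n_classes), b2 = rep(0, n_classes)
      )
    } else {
      H <- as.integer(hidden)
      list(
        Wc1 = init(kernel * d_in, channels), bc1 = rep(0, channels),
        Wx_f = init(channels, 4L * H), Wh_f = init(H, 4L * H), b_f = rep(0, 4L * H),
        Wx_b = init(channels, 4L * H), Wh_b = init(H, 4L * H), b_b = rep(0, 4L * H),
        Wc2 = init(kernel * 2L * H, n_classes), bc2 = rep(0, n_classes)
      )
    }
  })
  structure(list(architecture = architecture,
                 config = list(d_in = d_in, channels = as.integer(channels),
                               kernel = kernel, hidden = as.integer(hidden),
                               n_classes = as.integer(n_classes)),
                 params = params),
            class = c(paste0("emission_", architecture), "emission_model"))
}

#' @export
print.emission_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<emission_model: ", x$architecture, "> d_in = ", x$config$d_in,
      ", ", np, " parameters\n", sep = "")
  invisible(x)
}

# Internal: unfold a T x D matrix into T x (kernel*D) windows, zero padded.
im2col <- function(x, kernel) {
  T_ <- nrow(x); D <- ncol(x); r <- (kernel - 1L) %/% 2L
  xp <- rbind(matrix(0, r, D), x, matrix(0, r, D))
  out <- matrix(0, T_, kernel * D)
  for (k in seq_len(kernel))
    out[, ((k - 1L) * D + 1L):(k * D)] <- xp[k:(k + T_ - 1L), , drop = FALSE]
  out
}

# Internal: fold window gradients back onto the T x D input gradient.
col2im <- function(d_win, T_, D, kernel) {
  r <- (kernel - 1L) %/% 2L
  d_xp <- matrix(0, T_ + 2L * r, D)
  for (k in seq_len(kernel)) {
    cols <- ((k - 1L) * D + 1L):(k * D)
    d_xp[k:(k + T_ - 1L), ] <- d_xp[k:(k + T_ - 1L), , drop = FALSE] +
      d_win[, cols, drop = FALSE]
  }
  d_xp[(r + 1L):(r + T_), , drop = FALSE]
}

#' Emission-model forward pass
#'
#' @param model An [emission_model()].
#' @param x Numeric T x d_in input matrix.
#' @return List with `logits` (T x n_classes) and an opaque `cache` consumed
#'   by [emission_backward()].
#' @export
emission_forward <- function(model, x) UseMethod("emission_forward")

#' Emission-model backward pass
#'
#' @param model An [emission_model()].
#' @param x The input used in the forward pass.
#' @param cache The cache returned by [emission_forward()].
#' @param d_logits Gradient of the loss with respect to the logits.
#' @return Named list of parameter gradients (same shapes as `model$params`).
#' @export
emission_backward <- function(model, x, cache, d_logits)
  UseMethod("emission_backward")

#' @export
emission_forward.emission_conv <- function(model, x) {
  p <- model$params
  xc <- im2col(x, model$config$kernel)
  z1 <- sweep(xc %*% p$W1, 2, p$b1, "+")
  h <- pmax(z1, 0)
  logits <- sweep(h %*% p$W2, 2, p$b2, "+")
  list(logits = logits, cache = list(xc = xc, z1 = z1, h = h))
}

#' @export
emission_backward.emission_conv <- function(model, x, cache, d_logits) {
  p <- model$params
  d_h <- d_logits %*% t(p$W2)
  d_z1 <- d_h * (cache$z1 > 0)
  list(
    W1 = t(cache$xc) %*% d_z1, b1 = colSums(d_z1),
    W2 = t(cache$h) %*% d_logits, b2 = colSums(d_logits)
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Internal: one-directional LSTM over a T x D input; returns hidden states and
# the gate activations needed for backprop.
lstm_forward <- function(x, Wx, Wh, b, H) {
  T_ <- nrow(x)
  hs <- matrix(0, T_, H); cs <- matrix(0, T_, H)
  gi <- matrix(0, T_, H); gf <- matrix(0, T_, H)
  gg <- matrix(0, T_, H); go <- matrix(0, T_, H)
  h_prev <- rep(0, H); c_prev <- rep(0, H)
  z_x <- x %*% Wx
  for (t in seq_len(T_)) {
    z <- z_x[t, ] + as.numeric(h_prev %*% Wh) + b
    i <- sigmoid(z[1:H]); f <- sigmoid(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)]); o <- sigmoid(z[(3 * H + 1):(4 * H)])
    c_ <- f * c_prev + i * g
    h_ <- o * tanh(c_)
    gi[t, ] <- i; gf[t, ] <- f; gg[t, ] <- g; go[t, ] <- o
    cs[t, ] <- c_; hs[t, ] <- h_
    h_prev <- h_; c_prev <- c_
  }
  list(h = hs, c = cs, i = gi, f = gf, g = gg, o = go)
}

# Internal: backprop through lstm_forward. d_h is T x H (gradient w.r.t. the
# hidden outputs). Returns parameter gradients and the input gradient.
lstm_backward <- function(x, Wx, Wh, b, H, fw, d_h) {
  T_ <- nrow(x)
  d_Wx <- matrix(0, nrow(Wx), ncol(Wx)); d_Wh <- matrix(0, nrow(Wh), ncol(Wh))
  d_b <- rep(0, length(b)); d_x <- matrix(0, nrow(x), ncol(x))
  d_h_next <- rep(0, H); d_c_next <- rep(0, H)
  for (t in T_:1) {
    dh <- d_h[t, ] + d_h_next
    c_ <- fw$c[t, ]; tc <- tanh(c_)
    i <- fw$i[t, ]; f <- fw$f[t, ]; g <- fw$g[t, ]; o <- fw$o[t, ]
    dc <- dh * o * (1 - tc^2) + d_c_next
    c_prev <- if (t > 1L) fw$c[t - 1L, ] else rep(0, H)
    h_prev <- if (t > 1L) fw$h[t - 1L, ] else rep(0, H)
    d_i <- dc * g * i * (1 - i)
    d_f <- dc * c_prev * f * (1 - f)
    d_g <- dc * i * (1 - g^2)
    d_o <- dh * tc * o * (1 - o)
    d_z <- c(d_i, d_f, d_g, d_o)
    d_Wx <- d_Wx + outer(x[t, ], d_z)
    d_Wh <- d_Wh + outer(h_prev, d_z)
    d_b <- d_b + d_z
    d_x[t, ] <- as.numeric(Wx %*% d_z)
    d_h_next <- as.numeric(Wh %*% d_z)
    d_c_next <- dc * f
  }
  list(Wx = d_Wx, Wh = d_Wh, b = d_b, d_x = d_x)
}

#' @export
emission_forward.emission_cnn_lstm_cnn <- function(model, x) {
  p <- model$params
  H <- model$config$hidden
  k <- model$config$kernel
  xc <- im2col(x, k)
  z1 <- sweep(xc %*% p$Wc1, 2, p$bc1, "+")
  a1 <- pmax(z1, 0)
  fwd <- lstm_forward(a1, p$Wx_f, p$Wh_f, p$b_f, H)
  a1_rev <- a1[rev(seq_len(nrow(a1))), , drop = FALSE]
  bwd <- lstm_forward(a1_rev, p$Wx_b, p$Wh_b, p$b_b, H)
  h_bi <- cbind(fwd$h, bwd$h[rev(seq_len(nrow(bwd$h))), , drop = FALSE])
  hc <- im2col(h_bi, k)
  logits <- sweep(hc %*% p$Wc2, 2, p$bc2, "+")
  list(logits = logits,
       cache = list(xc = xc, z1 = z1, a1 = a1, a1_rev = a1_rev,
                    fwd = fwd, bwd = bwd, h_bi = h_bi, hc = hc))
}

#' @export
emission_backward.emission_cnn_lstm_cnn <- function(model, x, cache, d_logits) {
  p <- model$params
  H <- model$config$hidden
  k <- model$config$kernel
  T_ <- nrow(x)
  d_hc <- d_logits %*% t(p$Wc2)
  d_hbi <- col2im(d_hc, T_, 2L * H, k)
  d_hf <- d_hbi[, 1:H, drop = FALSE]
  d_hb_fwdorder <- d_hbi[, (H + 1):(2 * H), drop = FALSE]
  d_hb <- d_hb_fwdorder[rev(seq_len(T_)), , drop = FALSE]
  bf <- lstm_backward(cache$a1, p$Wx_f, p$Wh_f, p$b_f, H, cache$fwd, d_hf)
  bb <- lstm_backward(cache$a1_rev, p$Wx_b, p$Wh_b, p$b_b, H, cache$bwd, d_hb)
  d_a1 <- bf$d_x + bb$d_x[rev(seq_len(T_)), , drop = FALSE]
  d_z1 <- d_a1 * (cache$z1 > 0)
  list(
    Wc1 = t(cache$xc) %*% d_z1, bc1 = colSums(d_z1),
    Wx_f = bf$Wx, Wh_f = bf$Wh, b_f = bf$b,
    Wx_b = bb$Wx, Wh_b = bb$Wh, b_b = bb$b,
    Wc2 = t(cache$hc) %*% d_logits, bc2 = colSums(d_logits)
  )
}

#' Compute an emission matrix from an embedding matrix
#'
#' Convenience wrapper returning only the T x K logit matrix.
#'
#' @inheritParams emission_forward
#' @return Numeric T x n_classes matrix.
#' @export
emission_network_forward <- function(model, x) {
  emission_forward(model, x)$logits
}
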