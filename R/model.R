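# The BILSTM+ATT(+CHAR) network: embedding composition, bidirectional LSTM
# annotations, attention pooling, softmax output and cross-entropy loss.
#
# This file holds the model configuration, parameter initialization, and a
# straight-line per-message forward pass written for clarity. Training uses
# the vectorised mini-batch engine in batch.R; a test asserts the two paths
# agree to floating-point accuracy.

#' Model configuration
#'
#' Defaults follow the published training setup: 50-dimensional word and
#' character embeddings, 100 convolution kernels of width 5 for the
#' character pathway, 50 LSTM units per direction. The character table rows
#' are `char_dim`-dimensional (input side); the pooled character feature of
#' a word is `char_kernels`-dimensional (output side), so each input row of
#' the network is `word_dim + char_kernels` wide when `use_char` is on.
#'
#' @param word_dim word embedding dimension d.
#' @param char_dim character embedding dimension l.
#' @param char_kernels number of convolution kernels K.
#' @param kernel_width convolution region size w (characters per window).
#' @param lstm_units hidden units m per LSTM direction (annotations are 2m).
#' @param attn_dim attention projection size a; defaults to `2 * lstm_units`,
#'   matching the annotation size.
#' @param n_classes number of output classes.
#' @param use_char include the character pathway (`FALSE` gives the
#'   word-only BILSTM+ATT ablation — the identical code path minus the
#'   character features).
#' @param max_seq_len messages longer than this many tokens are truncated.
#' @param max_word_len words longer than this many characters are truncated
#'   in the character pathway.
#' @return object of class `hf_model_config`.
#' @export
model_config <- function(word_dim = 50L, char_dim = 50L, char_kernels = 100L,
                         kernel_width = 5L, lstm_units = 50L,
                         attn_dim = NULL, n_classes = 4L, use_char = TRUE,
                         max_seq_len = 64L, max_word_len = 24L) {
  cfg <- list(word_dim = as.integer(word_dim),
              char_dim = as.integer(char_dim),
              char_kernels = as.integer(char_kernels),
              kernel_width = as.integer(kernel_width),
              lstm_units = as.integer(lstm_units),
              attn_dim = as.integer(attn_dim %||% (2L * lstm_units)),
              n_classes = as.integer(n_classes),
              use_char = isTRUE(use_char),
              max_seq_len = as.integer(max_seq_len),
              max_word_len = as.integer(max_word_len))
  dims <- unlist(cfg[c("word_dim", "char_dim", "char_kernels", "kernel_width",
                       "lstm_units", "attn_dim", "n_classes", "max_seq_len",
                       "max_word_len")])
  if (any(dims < 1L)) stop_validation("all model dimensions must be positive")
  if (cfg$kernel_width > cfg$max_word_len) {
    stop_validation("kernel_width must not exceed max_word_len")
  }
  cfg$input_dim <- cfg$word_dim + if (cfg$use_char) cfg$char_kernels else 0L
  structure(cfg, class = "hf_model_config")
}

glorot <- function(nrow, ncol) {
  r <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

#' Initialize model parameters
#'
#' Word vectors found in a pretrained table copy those vectors; all other
#' word rows are sampled uniformly in \[-0.05, 0.05\], except the padding
#' row (fixed at zero, masked everywhere) and the unknown row (initialized
#' at zero, learned). Character vectors are uniform in \[-0.05, 0.05\] with
#' a zero padding row. LSTM and dense weights use Glorot-uniform
#' initialization; LSTM forget-gate biases start at 1.
#'
#' @param vocab an [build_vocabulary()] result.
#' @param config an [model_config()].
#' @param embeddings optional [read_embeddings()] table; its dimension must
#'   equal `config$word_dim`.
#' @param seed integer RNG seed (initialization is deterministic given it).
#' @return object of class `hf_model_params`: named list of numeric arrays
#'   plus the `config` and `vocab` used.
#' @export
init_params <- function(vocab, config, embeddings = NULL, seed = 1L) {
  stopifnot(inherits(vocab, "hf_vocabulary"), inherits(config, "hf_model_config"))
  with_seed(seed, {
    V <- length(vocab$word_index)
    Ch <- length(vocab$char_index)
    d <- config$word_dim
    l <- config$char_dim
    K <- config$char_kernels
    w <- config$kernel_width
    m <- config$lstm_units
    a <- config$attn_dim
    D <- config$input_dim

    E <- matrix(stats::runif(V * d, -0.05, 0.05), V, d)
    E[1L, ] <- 0  # padding row, fixed
    E[2L, ] <- 0  # unknown row, learned from zero
    n_pretrained <- 0L
    if (!is.null(embeddings)) {
      stopifnot(inherits(embeddings, "hf_embedding_table"))
      if (embeddings$dimension != d) {
        stop_validation("pretrained dimension %d != word_dim %d",
                        embeddings$dimension, d)
      }
      hit <- intersect(names(vocab$word_index), rownames(embeddings$vectors))
      hit <- setdiff(hit, c(PAD_TOKEN, UNK_TOKEN))
      if (length(hit) > 0L) {
        E[vocab$word_index[hit] + 1L, ] <- embeddings$vectors[hit, , drop = FALSE]
        n_pretrained <- length(hit)
      }
    }
    C <- matrix(stats::runif(Ch * l, -0.05, 0.05), Ch, l)
    C[1L, ] <- 0

    b_f <- rep(0, 4L * m); b_f[(m + 1L):(2L * m)] <- 1
    b_b <- rep(0, 4L * m); b_b[(m + 1L):(2L * m)] <- 1
    params <- list(
      E = E,
      C = C,
      Wc = glorot(w * l, K),
      bc = rep(0, K),
      Wx_f = glorot(D, 4L * m), Wh_f = glorot(m, 4L * m), b_f = b_f,
      Wx_b = glorot(D, 4L * m), Wh_b = glorot(m, 4L * m), b_b = b_b,
      Wa = glorot(2L * m, a), ba = rep(0, a),
      hhat = stats::runif(a, -0.05, 0.05),
      Wo = glorot(2L * m, config$n_classes), bo = rep(0, config$n_classes)
    )
    structure(list(params = params, config = config, vocab = vocab,
                   n_pretrained = n_pretrained, seed = as.integer(seed)),
              class = "hf_model_params")
  })
}

#' @export
print.hf_model_params <- function(x, ...) {
  n <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<hf_model_params> %s, %d parameters, |V|=%d, |C|=%d\n",
              if (x$config$use_char) "BILSTM+ATT+CHAR" else "BILSTM+ATT",
              n, length(x$vocab$word_index), length(x$vocab$char_index)))
  invisible(x)
}

# Character ids (1-based rows into C) for one word; unknown chars map to
# the UNK row, words are truncated at max_word_len.
char_ids <- function(word, vocab, config) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  if (length(ch) > config$max_word_len) ch <- ch[seq_len(config$max_word_len)]
  idx <- vocab$char_index[ch]
  idx[is.na(idx)] <- UNK_INDEX
  unname(idx) + 1L
}

#' Convolutional character embedding of one word
#'
#' The word's characters are looked up in the character table (unknown
#' characters use the unknown row), the sequence is right-padded with the
#' zero padding row to at least `kernel_width` positions, each kernel is
#' convolved over all valid windows, a tanh nonlinearity is applied, and
#' the result is max-pooled over positions.
#'
#' @param word a non-empty string.
#' @param model an [init_params()] object.
#' @return numeric vector of length `char_kernels`.
#' @export
char_embed <- function(word, model) {
  stopifnot(inherits(model, "hf_model_params"), nzchar(word))
  cfg <- model$config
  p <- model$params
  ids <- char_ids(word, model$vocab, cfg)
  w <- cfg$kernel_width
  if (length(ids) < w) ids <- c(ids, rep(1L, w - length(ids)))  # pad row
  P <- length(ids) - w + 1L
  out <- rep(-Inf, cfg$char_kernels)
  for (pos in seq_len(P)) {
    window <- as.numeric(t(p$C[ids[pos:(pos + w - 1L)], , drop = FALSE]))
    act <- tanh(drop(window %*% p$Wc) + p$bc)
    out <- pmax(out, act)
  }
  out
}

#' Compose the network input matrix for one message
#'
#' Row i is the word embedding of token i, concatenated (when the character
#' pathway is on) with its pooled convolutional character feature. Words
#' absent from the word vocabulary use the learned unknown row for the word
#' part while the character part is still computed from their spelling —
#' the mechanism that addresses out-of-vocabulary words. Token sequences
#' longer than `max_seq_len` are truncated.
#'
#' @param tokens character vector of tokens (or an `hf_tokens` object).
#' @param model an [init_params()] object.
#' @return numeric matrix with one row per (kept) token.
#' @export
compose_input <- function(tokens, model) {
  if (inherits(tokens, "hf_tokens")) tokens <- tokens$tokens
  if (length(tokens) == 0L) stop_validation("cannot compose input for zero tokens")
  cfg <- model$config
  if (length(tokens) > cfg$max_seq_len) tokens <- tokens[seq_len(cfg$max_seq_len)]
  wid <- model$vocab$word_index[tokens]
  wid[is.na(wid)] <- UNK_INDEX
  X <- model$params$E[unname(wid) + 1L, , drop = FALSE]
  if (cfg$use_char) {
    CF <- t(vapply(tokens, function(tok) char_embed(tok, model),
                   numeric(cfg$char_kernels)))
    X <- cbind(X, CF)
  }
  dimnames(X) <- NULL
  X
}

# One LSTM step. x: input vector; h, c: previous states; Wx (D x 4m),
# Wh (m x 4m), b (4m). Gate order along columns: input, forget, cell, output.
lstm_step <- function(x, h, c, Wx, Wh, b) {
  m <- length(h)
  g <- drop(x %*% Wx) + drop(h %*% Wh) + b
  i_g <- stats::plogis(g[1:m])
  f_g <- stats::plogis(g[(m + 1L):(2L * m)])
  c_t <- tanh(g[(2L * m + 1L):(3L * m)])
  o_g <- stats::plogis(g[(3L * m + 1L):(4L * m)])
  c_new <- f_g * c + i_g * c_t
  h_new <- o_g * tanh(c_new)
  list(h = h_new, c = c_new)
}

#' Bidirectional LSTM annotations
#'
#' Runs a forward and a backward LSTM over the input rows and concatenates
#' the two hidden states at each position into a 2m-dimensional word
#' annotation.
#'
#' @param X input matrix from [compose_input()].
#' @param model an [init_params()] object.
#' @return numeric matrix, one 2m-dimensional annotation per row of `X`.
#' @export
bilstm_annotate <- function(X, model) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  p <- model$params
  m <- model$config$lstm_units
  n <- nrow(X)
  Hf <- matrix(0, n, m)
  h <- rep(0, m); c <- rep(0, m)
  for (t in seq_len(n)) {
    st <- lstm_step(X[t, ], h, c, p$Wx_f, p$Wh_f, p$b_f)
    h <- st$h; c <- st$c
    Hf[t, ] <- h
  }
  Hb <- matrix(0, n, m)
  h <- rep(0, m); c <- rep(0, m)
  for (t in rev(seq_len(n))) {
    st <- lstm_step(X[t, ], h, c, p$Wx_b, p$Wh_b, p$b_b)
    h <- st$h; c <- st$c
    Hb[t, ] <- h
  }
  cbind(Hf, Hb)
}

#' Attention pooling over word annotations
#'
#' Each annotation is projected through a tanh layer, scored against a
#' learned context vector, and the softmax-normalized scores weight the
#' annotations into a single sentence embedding.
#'
#' @param H annotation matrix from [bilstm_annotate()].
#' @param model an [init_params()] object.
#' @return list with `s` (sentence embedding, length 2m) and `alpha`
#'   (attention weights, one per row of `H`, summing to 1).
#' @export
attend <- function(H, model) {
  stopifnot(is.matrix(H), nrow(H) >= 1L)
  p <- model$params
  Z <- tanh(sweep(H %*% p$Wa, 2L, p$ba, `+`))
  u <- drop(Z %*% p$hhat)
  alpha <- softmax(u)
  s <- drop(crossprod(H, alpha))
  list(s = s, alpha = alpha)
}

#' Forward pass for one message
#'
#' Composes the full network — embedding composition, bidirectional LSTM,
#' attention pooling, and softmax output — and exposes all intermediates
#' needed for visualization.
#'
#' @param tweet an `hf_tokens` object (or plain character vector of tokens).
#' @param model an [init_params()] object.
#' @return object of class `hf_forward`: `probabilities` (length
#'   `n_classes`, sums to 1), `predicted` (argmax class, ties to the lower
#'   index), `alpha` (per-token attention weights), `s` (sentence
#'   embedding), `annotations` (the per-token 2m matrix), `tokens`.
#' @export
predict_tweet <- function(tweet, model) {
  tokens <- if (inherits(tweet, "hf_tokens")) tweet$tokens else as.character(tweet)
  X <- compose_input(tokens, model)
  H <- bilstm_annotate(X, model)
  att <- attend(H, model)
  p <- model$params
  logits <- drop(att$s %*% p$Wo) + p$bo
  prob <- softmax(logits)
  structure(list(probabilities = prob,
                 predicted = which.max(prob),  # ties -> lower class index
                 alpha = att$alpha,
                 s = att$s,
                 annotations = H,
                 tokens = tokens[seq_len(nrow(X))]),
            class = "hf_forward")
}

#' Cross-entropy loss of a batch of predictions
#'
#' `L = -sum_d log p_d(y_d)` over the batch; both the sum (the objective as
#' stated) and the per-example mean (used for optimizer steps) are returned.
#' Probabilities are clamped at 1e-12 before the log, with a warning when
#' clamping occurs.
#'
#' @param results list of [predict_tweet()] results, or a numeric matrix of
#'   probabilities (one row per example).
#' @param labels integer true classes.
#' @return list with `sum` and `mean`.
#' @export
cross_entropy_loss <- function(results, labels) {
  P <- if (is.matrix(results)) results else
    t(vapply(results, `[[`, numeric(length(results[[1]]$probabilities)),
             "probabilities"))
  stopifnot(nrow(P) == length(labels), length(labels) >= 1L)
  py <- P[cbind(seq_len(nrow(P)), as.integer(labels))]
  if (any(py < 1e-12)) {
    warning("predicted probability of a true label clamped at 1e-12",
            call. = FALSE)
    py <- pmax(py, 1e-12)
  }
  s <- -sum(log(py))
  list(sum = s, mean = s / nrow(P))
}
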