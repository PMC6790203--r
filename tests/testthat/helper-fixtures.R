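# Shared fixtures and independent oracles. Oracles are deliberately written
# as straight-line / loop-based code, independent of the package's
# vectorised implementations.

make_tokens <- function(token_lists, labels = NULL, ids = NULL) {
  n <- length(token_lists)
  ids <- ids %||% sprintf("t%03d", seq_len(n))
  labels <- labels %||% rep(NA_integer_, n)
  structure(Map(function(id, tt, lab) {
    structure(list(id = id, tokens = as.character(tt),
                   label = as.integer(lab)), class = "hf_tokens")
  }, ids, token_lists, labels, USE.NAMES = FALSE),
  class = "hf_token_corpus")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small labeled corpus of pseudo-messages over a fixed vocabulary,
# deterministic given the seed.
random_token_corpus <- function(n = 40, seed = 1, vocab_words = NULL,
                                len = 2:6) {
  vocab_words <- vocab_words %||%
    c("hay", "fever", "sneeze", "pollen", "itchy", "eyes", "meds",
      "probs", "season", "windy", "news", "sale", "bottle", "footy")
  withr::with_seed(seed, {
    make_tokens(
      lapply(seq_len(n), function(i) {
        sample(vocab_words, sample(len, 1), replace = TRUE)
      }),
      labels = sample(1:4, n, replace = TRUE))
  })
}

tiny_config <- function(use_char = TRUE) {
  model_config(word_dim = 4, char_dim = 3, char_kernels = 5,
               kernel_width = 2, lstm_units = 3, n_classes = 4,
               use_char = use_char, max_seq_len = 16, max_word_len = 12)
}

tiny_model <- function(tokens, use_char = TRUE, seed = 3) {
  vocab <- build_vocabulary(tokens)
  init_params(vocab, tiny_config(use_char), seed = seed)
}

# ---- oracles -----------------------------------------------------------

# Run-length oracle for the repeat cap, built on base rle().
collapse_repeats_oracle <- function(token, max_repeat = 3L) {
  r <- rle(strsplit(token, "", fixed = TRUE)[[1]])
  r$lengths <- pmin(r$lengths, max_repeat)
  paste(inverse.rle(r), collapse = "")
}

# Loop-based confusion/metric oracle.
metrics_oracle <- function(truth, predicted, n_classes = 4L) {
  prec <- rec <- f1 <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    tp <- sum(truth == k & predicted == k)
    fp <- sum(truth != k & predicted == k)
    fn <- sum(truth == k & predicted != k)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) {
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
    } else 0
  }
  list(accuracy = 100 * sum(truth == predicted) / length(truth),
       macro_f1 = 100 * mean(f1), f1 = f1)
}

# Hand-coded single LSTM step: explicit gate arithmetic, scalar indexing.
lstm_step_oracle <- function(x, h_prev, c_prev, Wx, Wh, b, m) {
  g <- numeric(4 * m)
  for (j in seq_len(4 * m)) {
    g[j] <- sum(x * Wx[, j]) + sum(h_prev * Wh[, j]) + b[j]
  }
  sig <- function(v) 1 / (1 + exp(-v))
  i <- sig(g[1:m])
  f <- sig(g[(m + 1):(2 * m)])
  cand <- tanh(g[(2 * m + 1):(3 * m)])
  o <- sig(g[(3 * m + 1):(4 * m)])
  c_new <- f * c_prev + i * cand
  list(h = o * tanh(c_new), c = c_new)
}

# Straight-line forward oracle for a word-only model on one message:
# embeddings -> biLSTM -> attention -> softmax, all via explicit loops.
forward_oracle <- function(tokens, model) {
  p <- model$params
  cfg <- model$config
  m <- cfg$lstm_units
  n <- length(tokens)
  wid <- model$vocab$word_index[tokens]
  wid[is.na(wid)] <- 1L  # UNK (0-based)
  X <- p$E[unname(wid) + 1L, , drop = FALSE]
  Hf <- matrix(0, n, m); Hb <- matrix(0, n, m)
  h <- rep(0, m); c <- rep(0, m)
  for (t in 1:n) {
    st <- lstm_step_oracle(X[t, ], h, c, p$Wx_f, p$Wh_f, p$b_f, m)
    h <- st$h; c <- st$c; Hf[t, ] <- h
  }
  h <- rep(0, m); c <- rep(0, m)
  for (t in n:1) {
    st <- lstm_step_oracle(X[t, ], h, c, p$Wx_b, p$Wh_b, p$b_b, m)
    h <- st$h; c <- st$c; Hb[t, ] <- h
  }
  H <- cbind(Hf, Hb)
  u <- numeric(n)
  for (t in 1:n) {
    z <- tanh(drop(t(p$Wa) %*% H[t, ]) + p$ba)
    u[t] <- sum(z * p$hhat)
  }
  alpha <- exp(u - max(u)); alpha <- alpha / sum(alpha)
  s <- rep(0, 2 * m)
  for (t in 1:n) s <- s + alpha[t] * H[t, ]
  logits <- drop(t(p$Wo) %*% s) + p$bo
  e <- exp(logits - max(logits))
  list(p = e / sum(e), alpha = alpha, s = s)
}

# Zero out a (possibly nested) parameter array by name.
zero_param <- function(model, names) {
  for (nm in names) model$params[[nm]] <- model$params[[nm]] * 0
  model
}
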