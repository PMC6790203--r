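# The vectorised training engine must agree exactly with the per-message
# reference path, keep its distributions normalized, ignore padding, and
# produce gradients that match finite differences.

test_that("the batched forward pass equals the per-message reference path", {
  for (use_char in c(TRUE, FALSE)) {
    toks <- random_token_corpus(15, seed = 31, len = 1:7)
    model <- tiny_model(toks, use_char = use_char, seed = 13)
    enc <- hayfever:::encode_tokens(toks, model$vocab, model$config)
    fw <- hayfever:::forward_batch(enc, seq_along(toks), model)
    for (i in seq_along(toks)) {
      ref <- predict_tweet(toks[[i]], model)
      expect_equal(fw$probabilities[i, ], ref$probabilities, tolerance = 1e-10)
      n <- length(toks[[i]]$tokens)
      expect_equal(fw$alpha[i, seq_len(n)], ref$alpha, tolerance = 1e-10)
    }
  }
})

test_that("padding positions carry zero attention and cannot alter outputs", {
  toks <- random_token_corpus(30, seed = 32, len = 1:8)
  model <- tiny_model(toks, use_char = TRUE, seed = 14)
  enc <- hayfever:::encode_tokens(toks, model$vocab, model$config)
  # same message evaluated alone (no padding) and inside a batch padded to
  # the longest member
  fw_all <- hayfever:::forward_batch(enc, seq_along(toks), model)
  for (i in seq_along(toks)) {
    alone <- hayfever:::forward_batch(enc, i, model)
    expect_equal(fw_all$probabilities[i, ], alone$probabilities[1, ],
                 tolerance = 1e-10)
    n <- length(toks[[i]]$tokens)
    if (n < ncol(fw_all$alpha)) {
      expect_equal(fw_all$alpha[i, (n + 1):ncol(fw_all$alpha)],
                   rep(0, ncol(fw_all$alpha) - n))
    }
  }
})

test_that("probabilities and attention stay normalized over many random configurations", {
  set.seed(77)
  checked <- 0L
  for (rep in 1:40) {
    cfg <- model_config(word_dim = sample(2:6, 1), char_dim = sample(2:4, 1),
                        char_kernels = sample(2:6, 1), kernel_width = sample(2:3, 1),
                        lstm_units = sample(2:5, 1),
                        use_char = sample(c(TRUE, FALSE), 1),
                        max_seq_len = 12, max_word_len = 10)
    toks <- random_token_corpus(30, seed = 1000 + rep, len = 1:6)
    vocab <- build_vocabulary(toks)
    model <- init_params(vocab, cfg, seed = rep)
    enc <- hayfever:::encode_tokens(toks, vocab, cfg)
    fw <- hayfever:::forward_batch(enc, seq_along(toks), model)
    expect_true(all(fw$probabilities >= 0))
    expect_equal(rowSums(fw$probabilities), rep(1, 30), tolerance = 1e-6)
    expect_true(all(fw$alpha >= 0))
    expect_equal(rowSums(fw$alpha), rep(1, 30), tolerance = 1e-6)
    expect_equal(rowSums(fw$alpha * (1 - fw$mask)), rep(0, 30))
    checked <- checked + 2L * 30L
  }
  expect_gte(checked, 1000L)  # at least 1000 random message checks
})

test_that("analytic gradients match central finite differences", {
  for (use_char in c(TRUE, FALSE)) {
    toks <- random_token_corpus(6, seed = 41, len = 2:5)
    model <- tiny_model(toks, use_char = use_char, seed = 15)
    labels <- withr::with_seed(42, sample(1:4, 6, replace = TRUE))
    enc <- hayfever:::encode_tokens(toks, model$vocab, model$config)
    fw <- hayfever:::forward_batch(enc, 1:6, model, keep_cache = TRUE)
    grads <- hayfever:::backward_batch(fw, labels, model)
    lossfun <- function(m) {
      f <- hayfever:::forward_batch(enc, 1:6, m)
      cross_entropy_loss(f$probabilities, labels)$mean
    }
    eps <- 1e-5
    withr::with_seed(43, {
      for (nm in names(grads)) {
        g <- grads[[nm]]
        for (j in sample(length(g), min(8, length(g)))) {
          up <- model; up$params[[nm]][j] <- up$params[[nm]][j] + eps
          dn <- model; dn$params[[nm]][j] <- dn$params[[nm]][j] - eps
          num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
          rel <- abs(num - g[j]) / max(1e-6, abs(num) + abs(g[j]))
          expect_lt(rel, 1e-4)
        }
      }
    })
  }
})

test_that("the fixed rows of the embedding tables receive no gradient", {
  toks <- random_token_corpus(8, seed = 44, len = 2:4)
  model <- tiny_model(toks, use_char = TRUE, seed = 16)
  labels <- rep(1:4, 2)
  enc <- hayfever:::encode_tokens(toks, model$vocab, model$config)
  fw <- hayfever:::forward_batch(enc, 1:8, model, keep_cache = TRUE)
  grads <- hayfever:::backward_batch(fw, labels, model)
  expect_equal(grads$E[1, ], rep(0, model$config$word_dim))
  expect_equal(grads$C[1, ], rep(0, model$config$char_dim))
})

test_that("bulk prediction agrees with per-message prediction", {
  toks <- random_token_corpus(23, seed = 51, len = 1:6)
  model <- tiny_model(toks, use_char = TRUE, seed = 17)
  bulk <- predict_corpus(toks, model, batch_size = 7)
  for (i in seq_along(toks)) {
    ref <- predict_tweet(toks[[i]], model)
    expect_equal(bulk$probabilities[i, ], ref$probabilities, tolerance = 1e-10)
    expect_identical(bulk$predicted[i], ref$predicted)
  }
})
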