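test_that("character embedding obeys the shape contract and the zero fixed point", {
  toks <- make_tokens(list(c("hay", "ab", "antihistamine")))
  model <- tiny_model(toks)
  K <- model$config$char_kernels
  expect_length(char_embed("ab", model), K)       # shorter than kernel width
  expect_length(char_embed("antihistamine", model), K)
  zero <- zero_param(model, c("Wc", "bc"))
  expect_equal(char_embed("hay", zero), rep(0, K))  # tanh(0) = 0, max over 0s
})

test_that("a width-1 identity kernel reproduces hand-computed convolution", {
  # one kernel of width 1 over a 1-dimensional char table: the pooled value
  # is tanh(max(char values) + bias)
  toks <- make_tokens(list(c("ab", "ba")))
  vocab <- build_vocabulary(toks)
  cfg <- model_config(word_dim = 2, char_dim = 1, char_kernels = 1,
                      kernel_width = 1, lstm_units = 2, max_word_len = 8)
  model <- init_params(vocab, cfg, seed = 1)
  model$params$C[vocab$char_index["a"] + 1L, 1] <- 0.2
  model$params$C[vocab$char_index["b"] + 1L, 1] <- 0.7
  model$params$Wc <- matrix(1, 1, 1)
  model$params$bc <- 0.1
  expect_equal(char_embed("ab", model), tanh(0.7 + 0.1), tolerance = 1e-12)
  expect_equal(char_embed("a", model), tanh(0.2 + 0.1), tolerance = 1e-12)
})

test_that("input composition concatenates word and character features", {
  toks <- make_tokens(list(c("hay", "fever", "pollen")))
  model <- tiny_model(toks, use_char = TRUE)
  X <- compose_input(c("hay", "fever", "pollen"), model)
  expect_identical(dim(X), c(3L, model$config$word_dim + model$config$char_kernels))
  word_only <- tiny_model(toks, use_char = FALSE)
  Xw <- compose_input(c("hay", "fever", "pollen"), word_only)
  expect_identical(dim(Xw), c(3L, word_only$config$word_dim))
  expect_error(compose_input(character(0), model), class = "hf_validation_error")
})

test_that("an out-of-vocabulary word gets the unknown row plus its own character feature", {
  # training words cover the characters of the probe spellings, so the two
  # probes differ in indexed (not unknown) characters
  toks <- make_tokens(list(c("hay", "fever", "zips", "orbs")))
  model <- tiny_model(toks, use_char = TRUE)
  d <- model$config$word_dim
  X <- compose_input("probs", model)
  unk_row <- model$params$E[2L, ]
  expect_equal(X[1, 1:d], unk_row)
  expect_equal(X[1, -(1:d)], char_embed("probs", model))
  # char part depends on spelling; word part does not (checked with enough
  # kernels that coincidental pooling ties cannot mask the difference)
  X2 <- compose_input("probz", model)
  expect_equal(X2[1, 1:d], unk_row)
  wide <- init_params(model$vocab,
                      model_config(word_dim = 4, char_dim = 3,
                                   char_kernels = 16, kernel_width = 2,
                                   lstm_units = 3, max_word_len = 12),
                      seed = 8)
  expect_false(isTRUE(all.equal(char_embed("probs", wide),
                                char_embed("probz", wide))))
  # the word-only ablation cannot distinguish the two spellings
  wo <- tiny_model(toks, use_char = FALSE)
  expect_equal(compose_input("probs", wo), compose_input("probz", wo))
})

test_that("biLSTM annotations match a hand-coded gate-arithmetic oracle", {
  toks <- make_tokens(list(c("hay", "fever", "sneeze")))
  model <- tiny_model(toks, use_char = FALSE, seed = 11)
  m <- model$config$lstm_units
  # single token: one forward step and one backward step from zero states
  X1 <- compose_input("hay", model)
  H1 <- bilstm_annotate(X1, model)
  p <- model$params
  of <- lstm_step_oracle(X1[1, ], rep(0, m), rep(0, m), p$Wx_f, p$Wh_f, p$b_f, m)
  ob <- lstm_step_oracle(X1[1, ], rep(0, m), rep(0, m), p$Wx_b, p$Wh_b, p$b_b, m)
  expect_equal(drop(H1), c(of$h, ob$h), tolerance = 1e-8)
  # multi-token sequence against the full straight-line oracle
  X3 <- compose_input(c("hay", "fever", "sneeze"), model)
  H3 <- bilstm_annotate(X3, model)
  orc <- forward_oracle(c("hay", "fever", "sneeze"), model)
  expect_equal(predict_tweet(c("hay", "fever", "sneeze"), model)$probabilities,
               orc$p, tolerance = 1e-8)
  # zero-parameter fixed point
  zero <- zero_param(model, c("Wx_f", "Wh_f", "b_f", "Wx_b", "Wh_b", "b_b"))
  expect_equal(bilstm_annotate(X3, zero), matrix(0, 3, 2 * m))
})

test_that("tied weights on a reversed input swap the annotation halves", {
  toks <- make_tokens(list(c("hay", "fever")))
  model <- tiny_model(toks, use_char = FALSE, seed = 2)
  model$params$Wx_b <- model$params$Wx_f
  model$params$Wh_b <- model$params$Wh_f
  model$params$b_b <- model$params$b_f
  m <- model$config$lstm_units
  H_ab <- bilstm_annotate(compose_input(c("hay", "fever"), model), model)
  H_ba <- bilstm_annotate(compose_input(c("fever", "hay"), model), model)
  expect_equal(H_ab[, 1:m], H_ba[2:1, (m + 1):(2 * m)], tolerance = 1e-12)
})

test_that("attention reduces to closed forms at degenerate parameters", {
  toks <- make_tokens(list(c("hay", "fever", "sneeze", "pollen")))
  model <- tiny_model(toks, use_char = FALSE, seed = 5)
  X <- compose_input(c("hay", "fever", "sneeze", "pollen"), model)
  H <- bilstm_annotate(X, model)
  uniform <- attend(H, zero_param(model, c("Wa", "ba")))
  expect_equal(uniform$alpha, rep(0.25, 4), tolerance = 1e-12)
  single <- attend(H[1, , drop = FALSE], model)
  expect_equal(single$alpha, 1)
  expect_equal(single$s, H[1, ], tolerance = 1e-12)
  # scores (ln 2, 0) give weights (2/3, 1/3)
  expect_equal(hayfever:::softmax(c(log(2), 0)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("output layer closed forms hold and argmax ties break low", {
  toks <- make_tokens(list(c("hay", "fever")))
  model <- tiny_model(toks, use_char = FALSE, seed = 6)
  uni <- zero_param(model, c("Wo", "bo"))
  fw <- predict_tweet(c("hay", "fever"), uni)
  expect_equal(fw$probabilities, rep(0.25, 4), tolerance = 1e-12)
  expect_identical(fw$predicted, 1L)  # uniform ties go to class 1
  biased <- zero_param(model, "Wo")
  biased$params$bo <- c(10, 0, 0, 0)
  expect_identical(predict_tweet(c("hay", "fever"), biased)$predicted, 1L)
})

test_that("cross-entropy matches its closed forms and clamps zeros", {
  onehot <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(cross_entropy_loss(onehot, 1L)$sum, 0)
  expect_equal(cross_entropy_loss(matrix(0.25, 1, 4), 2L)$sum, log(4),
               tolerance = 1e-12)
  two <- matrix(c(0.5, 0.5, 0, 0, 0.5, 0.5, 0, 0), 2, byrow = TRUE)
  expect_equal(cross_entropy_loss(two, c(1L, 2L))$sum, 2 * log(2),
               tolerance = 1e-12)
  expect_equal(cross_entropy_loss(two, c(1L, 2L))$mean, log(2),
               tolerance = 1e-12)
  expect_warning(l0 <- cross_entropy_loss(onehot, 2L), "clamped")
  expect_true(is.finite(l0$sum))
})

test_that("checkpoints round-trip predictions exactly", {
  toks <- random_token_corpus(10, seed = 21)
  model <- tiny_model(toks, use_char = TRUE, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  probe <- toks[[1]]
  expect_identical(predict_tweet(probe, back)$probabilities,
                   predict_tweet(probe, model)$probabilities)
  expect_identical(back$vocab$word_index, model$vocab$word_index)
})

test_that("pretrained vectors are copied into matching rows", {
  toks <- make_tokens(list(c("hay", "fever")))
  vocab <- build_vocabulary(toks)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste("hay", paste(1:4 / 10, collapse = " ")),
               paste("absent", paste(5:8 / 10, collapse = " "))), path)
  emb <- read_embeddings(path)
  model <- init_params(vocab, tiny_config(use_char = FALSE), emb, seed = 1)
  expect_equal(model$params$E[vocab$word_index["hay"] + 1L, ], 1:4 / 10)
  expect_identical(model$n_pretrained, 1L)
  expect_error(init_params(vocab, model_config(word_dim = 7, use_char = FALSE),
                           emb, seed = 1),
               class = "hf_validation_error")
})
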