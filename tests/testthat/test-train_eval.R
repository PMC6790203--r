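test_that("stratified folds balance sizes and class counts within one", {
  # the published class counts: 8 folds of 386 and 2 of 387
  labels <- rep(1:4, c(719, 1823, 938, 382))
  toks <- make_tokens(as.list(rep("hayfever", length(labels))), labels = labels)
  fa <- stratified_folds(toks, 10, seed = 4)
  sizes <- tabulate(unname(fa) + 1L, 10)
  expect_identical(sort(sizes), c(rep(386L, 8), rep(387L, 2)))
  for (cl in 1:4) {
    per_fold <- tabulate(unname(fa)[labels == cl] + 1L, 10)
    expect_lte(max(per_fold) - min(per_fold), 1L)
    prop <- sum(labels == cl) / 10
    expect_true(all(abs(per_fold - prop) <= 1))
  }
  # determinism and exact divisibility
  expect_identical(stratified_folds(toks, 10, seed = 4), fa)
  even <- make_tokens(as.list(rep("x", 40)), labels = rep(1:4, each = 10))
  fe <- stratified_folds(even, 10, seed = 1)
  for (cl in 1:4) {
    expect_identical(tabulate(unname(fe)[rep(1:4, each = 10) == cl] + 1L, 10),
                     rep(1L, 10))
  }
  expect_error(stratified_folds(even, 41, seed = 1),
               class = "hf_validation_error")
  expect_warning(stratified_folds(make_tokens(as.list(rep("x", 6)),
                                              labels = c(1, 1, 1, 1, 2, 2)),
                                  3, seed = 1),
                 "fewer than")
})

test_that("metrics match hand-computed confusion arithmetic", {
  # truth (1,1,2,2) vs (1,2,2,2): class-1 F1 = 2/3, class-2 F1 = 0.8
  ev <- evaluate_predictions(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 2L),
                             n_classes = 2L)
  expect_equal(ev$per_class$f1, c(2 / 3, 0.8), tolerance = 1e-12)
  expect_equal(ev$macro_f1, 100 * mean(c(2 / 3, 0.8)), tolerance = 1e-12)
  expect_equal(ev$accuracy, 75)
  perfect <- evaluate_predictions(rep(1:4, 3), rep(1:4, 3))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$macro_f1, 100)
  # a truth class never predicted contributes F1 = 0
  missing <- evaluate_predictions(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 3L))
  expect_equal(missing$per_class$f1[4], 0)
  # internal identities
  expect_identical(rowSums(missing$confusion),
                   stats::setNames(rep(1, 4), 1:4))
  expect_equal(missing$accuracy, 100 * sum(diag(missing$confusion)) /
                 sum(missing$confusion))
})

test_that("metrics equal an independent loop-based oracle on random pairs", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      truth <- sample(1:4, 200, replace = TRUE)
      pred <- ifelse(stats::runif(200) < 0.3, truth,
                     sample(1:4, 200, replace = TRUE))
      ev <- evaluate_predictions(truth, pred)
      orc <- metrics_oracle(truth, pred)
      expect_identical(ev$accuracy, orc$accuracy)
      expect_identical(ev$macro_f1, orc$macro_f1)
      expect_identical(ev$per_class$f1, orc$f1)
    }
  })
})

test_that("training respects the epoch cap and is deterministic under a seed", {
  toks <- random_token_corpus(60, seed = 61, len = 2:6)
  tc <- train_config(folds = 2, repeats = 1, max_epochs = 1, patience = 10,
                     batch_size = 16, seed = 5)
  m1 <- train_fold(toks, tc, tiny_config(), seed = 5)
  expect_identical(nrow(attr(m1, "history")), 1L)
  m2 <- train_fold(toks, tc, tiny_config(), seed = 5)
  expect_identical(m1$params, m2$params)  # bit-identical
  m3 <- train_fold(toks, tc, tiny_config(), seed = 6)
  expect_false(identical(m1$params, m3$params))
})

test_that("training fits an easily separable two-class problem", {
  # two classes with disjoint vocabularies: the network should reach 100%
  # training accuracy well before the epoch cap
  withr::with_seed(8, {
    toks <- make_tokens(
      lapply(1:100, function(i) {
        pool <- if (i <= 50) c("sneeze", "pollen", "itchy") else
          c("bottle", "footy", "pizza")
        sample(pool, sample(3:5, 1), replace = TRUE)
      }),
      labels = rep(c(1L, 2L), each = 50))
  })
  tc <- train_config(folds = 2, repeats = 1, max_epochs = 60, patience = 60,
                     batch_size = 16, seed = 2)
  cfg <- model_config(word_dim = 8, char_dim = 4, char_kernels = 8,
                      kernel_width = 2, lstm_units = 6, n_classes = 4,
                      use_char = FALSE)
  model <- train_fold(toks, tc, cfg, seed = 2)
  ev <- evaluate_model(model, toks)
  expect_equal(ev$accuracy, 100)
})

test_that("early stopping restores the best-validation epoch", {
  toks <- random_token_corpus(80, seed = 62, len = 2:5)
  tc <- train_config(folds = 2, repeats = 1, max_epochs = 30, patience = 3,
                     batch_size = 16, seed = 7)
  model <- train_fold(toks, tc, tiny_config(use_char = FALSE), seed = 7)
  h <- attr(model, "history")
  best <- attr(model, "best_epoch")
  expect_identical(which.min(h$val_loss), as.integer(best))
  # stopped within patience of the best epoch, never past the cap
  expect_lte(nrow(h), 30L)
  expect_lte(nrow(h) - best, 3L)
})

test_that("test folds never leak into training: sentinel tokens change nothing", {
  toks <- random_token_corpus(50, seed = 63, len = 2:5)
  fa <- stratified_folds(toks, 2, seed = 9)
  train_part <- toks[unname(fa) != 0]
  test_part <- toks[unname(fa) == 0]
  vocab <- build_vocabulary(train_part)
  # sentinel-augmented test fold: unique tokens absent from training
  poisoned <- make_tokens(
    lapply(test_part, function(t) c(t$tokens, "zzqsentinelzzq")),
    labels = token_labels(test_part))
  expect_false("zzqsentinelzzq" %in% names(vocab$word_index))
  tc <- train_config(folds = 2, repeats = 1, max_epochs = 2, patience = 10,
                     batch_size = 16, seed = 9)
  m1 <- train_fold(train_part, tc, tiny_config(), seed = 9)
  m2 <- train_fold(train_part, tc, tiny_config(), seed = 9)
  expect_identical(m1$params, m2$params)
  # the poisoned fold still evaluates (sentinels go through UNK + chars)
  ev <- evaluate_model(m1, poisoned)
  expect_true(is.finite(ev$accuracy))
})

test_that("cross-validation bookkeeping holds on a tiny fixture", {
  toks <- random_token_corpus(48, seed = 64, len = 2:5)
  tc <- train_config(folds = 2, repeats = 1, max_epochs = 2, patience = 10,
                     batch_size = 16, seed = 10)
  rep <- cross_validate(toks, tc, tiny_config(use_char = FALSE))
  expect_identical(nrow(rep$per_run), 2L)
  expect_equal(rep$aggregate$accuracy_mean, mean(rep$per_run$accuracy))
  # weighted fold aggregation equals pooled-confusion accuracy
  expect_equal(rep$aggregate$accuracy_weighted,
               rep$aggregate$pooled_accuracy_mean, tolerance = 1e-9)
  expect_equal(sum(rep$confusion), 48)
  expect_s3_class(rep$oov, "hf_oov_report")
  # confusion row sums equal true class counts
  labs <- vapply(toks, `[[`, integer(1), "label")
  expect_identical(unname(rowSums(rep$confusion)),
                   as.numeric(tabulate(labs, 4)))
})
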