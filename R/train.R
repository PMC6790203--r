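# Stratified cross-validation training with early stopping, and
# accuracy / macro-F1 evaluation.

#' Training configuration
#'
#' Defaults follow the published protocol: stratified 10-fold
#' cross-validation, a 10% validation split inside each training part,
#' mini-batches of 64, the Adam optimizer, early stopping with patience 10,
#' and 5 repeats under different random initializations.
#'
#' @param folds number of cross-validation folds.
#' @param val_fraction fraction of the training part held out for early
#'   stopping (stratified).
#' @param batch_size mini-batch size.
#' @param patience epochs without validation-loss improvement before
#'   stopping. Improvement means strictly lower than the best seen; the
#'   best-epoch weights are restored.
#' @param repeats independent training repetitions (seed = base seed +
#'   repeat index).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param max_epochs safety cap on epochs.
#' @param min_count vocabulary pruning threshold (default 1: none).
#' @param seed base RNG seed.
#' @param verbose log per-epoch losses via `message()`.
#' @return object of class `hf_train_config`.
#' @export
train_config <- function(folds = 10L, val_fraction = 0.1, batch_size = 64L,
                         patience = 10L, repeats = 5L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         max_epochs = 200L, min_count = 1L, seed = 42L,
                         verbose = FALSE) {
  if (!(val_fraction > 0 && val_fraction < 1)) {
    stop_validation("val_fraction must be in (0, 1)")
  }
  if (!is_count(folds, 2L)) stop_validation("folds must be >= 2")
  if (!is_count(repeats, 1L)) stop_validation("repeats must be >= 1")
  structure(list(folds = as.integer(folds), val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 repeats = as.integer(repeats),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, max_epochs = as.integer(max_epochs),
                 min_count = as.integer(min_count), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "hf_train_config")
}

#' Stratified fold assignment
#'
#' Within each class, members are shuffled under the seed and dealt
#' round-robin to folds; the dealing pointer continues across classes so
#' that global fold sizes differ by at most one while per-class counts per
#' fold stay within one of proportional allocation.
#'
#' @param tokens a labeled `hf_token_corpus` (or [corpus()]).
#' @param k number of folds.
#' @param seed RNG seed; the assignment is deterministic given it.
#' @return object of class `hf_fold_assignment`: named integer vector
#'   mapping message id to fold index `0..k-1`.
#' @export
stratified_folds <- function(tokens, k, seed = 42L) {
  if (inherits(tokens, "hf_corpus")) {
    ids <- tokens$id
    labels <- tokens$label
  } else {
    ids <- vapply(tokens, `[[`, character(1), "id")
    labels <- token_labels(tokens)
  }
  if (anyNA(labels)) stop_validation("stratified_folds requires labels")
  n <- length(ids)
  if (k > n) stop_validation("k = %d exceeds corpus size %d", k, n)
  classes <- sort(unique(labels))
  small <- classes[vapply(classes, function(cl) sum(labels == cl) < k, logical(1))]
  if (length(small) > 0L) {
    warning(sprintf("class(es) %s have fewer than %d members; their folds will be uneven",
                    paste(small, collapse = ", "), k), call. = FALSE)
  }
  assignment <- integer(n)
  with_seed(seed, {
    ptr <- 0L
    for (cl in classes) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      assignment[members] <- (ptr + seq_along(members) - 1L) %% k
      ptr <- (ptr + length(members)) %% k
    }
  })
  structure(stats::setNames(assignment, ids), class = "hf_fold_assignment")
}

# ---- metrics -----------------------------------------------------------

#' Classification metrics from truth and predictions
#'
#' Accuracy is the percentage of correct predictions; per-class F1 is the
#' harmonic mean of precision and recall with the 0/0 convention F1 = 0;
#' macro-F1 is the unweighted mean of the per-class F1 values, as a
#' percentage.
#'
#' @param truth integer true classes.
#' @param predicted integer predicted classes.
#' @param n_classes number of classes.
#' @return object of class `hf_eval`: list with `accuracy`, `macro_f1`
#'   (percentages), `per_class` (data frame of precision/recall/F1), and
#'   `confusion` (rows = truth, columns = predicted).
#' @export
evaluate_predictions <- function(truth, predicted, n_classes = 4L) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1L)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = seq_len(n_classes),
                               predicted = seq_len(n_classes)))
  for (i in seq_along(truth)) {
    cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  }
  metrics_from_confusion(cm)
}

#' @rdname evaluate_predictions
#' @param cm square confusion matrix (rows = truth, columns = predicted).
#' @export
metrics_from_confusion <- function(cm) {
  n_classes <- nrow(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    accuracy = 100 * sum(tp) / sum(cm),
    macro_f1 = 100 * mean(f1),
    per_class = data.frame(class = seq_len(n_classes), precision = unname(prec),
                           recall = unname(rec), f1 = unname(f1)),
    confusion = cm,
    n = sum(cm)
  ), class = "hf_eval")
}

#' @export
print.hf_eval <- function(x, ...) {
  cat(sprintf("<hf_eval> n = %d, accuracy = %.2f%%, macro-F1 = %.2f%%\n",
              x$n, x$accuracy, x$macro_f1))
  invisible(x)
}

#' Evaluate a trained model on a labeled test set
#'
#' @param model a trained [init_params()] object.
#' @param tokens labeled `hf_token_corpus`.
#' @param batch_size forward batch size.
#' @return an `hf_eval` (see [evaluate_predictions()]).
#' @export
evaluate_model <- function(model, tokens, batch_size = 256L) {
  labels <- token_labels(tokens)
  if (anyNA(labels)) stop_validation("evaluate_model requires labeled input")
  pred <- predict_corpus(tokens, model, batch_size)
  evaluate_predictions(labels, pred$predicted,
                       n_classes = model$config$n_classes)
}

# ---- single-fold training ---------------------------------------------

# Stratified validation split: returns list(train_idx, val_idx).
val_split <- function(labels, val_fraction, seed) {
  with_seed(seed, {
    n <- length(labels)
    val <- integer(0)
    classes <- sort(unique(labels))
    degenerate <- any(vapply(classes, function(cl) sum(labels == cl) < 2L,
                             logical(1)))
    if (degenerate) {
      warning("a class has fewer than 2 training members; validation split is unstratified",
              call. = FALSE)
      val <- sample.int(n, max(1L, round(val_fraction * n)))
    } else {
      for (cl in classes) {
        members <- which(labels == cl)
        n_val <- max(1L, round(val_fraction * length(members)))
        val <- c(val, members[sample.int(length(members))][seq_len(n_val)])
      }
    }
    list(train_idx = setdiff(seq_len(n), val), val_idx = sort(val))
  })
}

#' Train the network on one training set
#'
#' Builds the vocabulary from the training data, carves out a stratified
#' validation split, and runs mini-batch Adam on the cross-entropy
#' objective with early stopping on validation loss: training stops when
#' the validation loss has not strictly improved for `patience` consecutive
#' epochs (or `max_epochs` is reached), and the parameters from the
#' best-validation-loss epoch are returned.
#'
#' @param tokens labeled training `hf_token_corpus`.
#' @param config an [train_config()].
#' @param model_config an [model_config()].
#' @param embeddings optional pretrained [read_embeddings()] table.
#' @param seed RNG seed for this training run (defaults to the config
#'   seed); initialization, splits and shuffling all derive from it.
#' @return a trained `hf_model_params`, with attribute `history` (data
#'   frame of per-epoch train/validation loss) and `best_epoch`.
#' @export
train_fold <- function(tokens, config = train_config(),
                       model_config = model_config(), embeddings = NULL,
                       seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  labels <- token_labels(tokens)
  if (anyNA(labels)) stop_validation("train_fold requires labeled input")
  vocab <- build_vocabulary(tokens, min_count = config$min_count)
  model <- init_params(vocab, model_config, embeddings, seed = seed)
  enc <- encode_tokens(tokens, vocab, model_config)
  sp <- val_split(labels, config$val_fraction, seed = seed + 1L)
  tr <- sp$train_idx
  va <- sp$val_idx
  state <- adam_init(model$params)
  best_loss <- Inf
  best_params <- model$params
  best_epoch <- 0L
  stall <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  with_seed(seed + 2L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- tr[sample.int(length(tr))]
      ep_loss <- 0
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        sel <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        fw <- forward_batch(enc, sel, model, keep_cache = TRUE)
        ep_loss <- ep_loss +
          cross_entropy_loss(fw$probabilities, enc$labels[sel])$sum
        grads <- backward_batch(fw, enc$labels[sel], model)
        upd <- adam_step(model$params, grads, state,
                         lr = config$learning_rate, beta1 = config$beta1,
                         beta2 = config$beta2, eps = config$epsilon)
        model$params <- upd$params
        state <- upd$state
      }
      val_loss <- 0
      for (start in seq(1L, length(va), by = 256L)) {
        sel <- va[start:min(start + 255L, length(va))]
        fw <- forward_batch(enc, sel, model)
        val_loss <- val_loss +
          cross_entropy_loss(fw$probabilities, enc$labels[sel])$sum
      }
      val_loss <- val_loss / length(va)
      history[epoch, ] <- list(epoch, ep_loss / length(tr), val_loss)
      if (config$verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        ep_loss / length(tr), val_loss))
      }
      if (val_loss < best_loss) {
        best_loss <- val_loss
        best_params <- model$params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  model$params <- best_params
  attr(model, "history") <- history
  attr(model, "best_epoch") <- best_epoch
  model
}

# ---- cross-validation --------------------------------------------------

#' Repeated stratified cross-validation
#'
#' For each repeat (seed = base seed + repeat index) and each fold: the
#' vocabulary is built from the training part only, the network is trained
#' with early stopping, and the held-out fold is evaluated. Aggregates are
#' reported two ways — mean of per-fold metrics, and metrics of the pooled
#' per-repeat confusion matrix — together with an OOV audit over the same
#' folds.
#'
#' @param tokens labeled `hf_token_corpus`.
#' @param config an [train_config()].
#' @param model_config an [model_config()].
#' @param embeddings optional pretrained table.
#' @return object of class `hf_eval_report`: `per_run` (data frame with one
#'   row per repeat x fold), `aggregate` (means and sds), `pooled`
#'   (per-repeat pooled metrics), `confusion` (summed), `per_class`
#'   (averaged), `oov` (an `hf_oov_report`), `fold_assignment`.
#' @export
cross_validate <- function(tokens, config = train_config(),
                           model_config = model_config(),
                           embeddings = NULL) {
  labels <- token_labels(tokens)
  if (anyNA(labels)) stop_validation("cross_validate requires labeled input")
  k <- config$folds
  fa <- stratified_folds(tokens, k, seed = config$seed)
  fold_of <- unname(fa)
  folds <- lapply(0:(k - 1L), function(f) {
    list(train = tokens[fold_of != f], test = tokens[fold_of == f])
  })
  oov <- oov_report(folds, expected_folds = k, min_count = config$min_count)
  per_run <- data.frame()
  pooled <- data.frame()
  confusion <- NULL
  per_class_acc <- NULL
  for (r in seq_len(config$repeats) - 1L) {
    seed_r <- config$seed + r
    cm_r <- NULL
    for (f in seq_len(k) - 1L) {
      model <- train_fold(folds[[f + 1L]]$train, config, model_config,
                          embeddings, seed = seed_r)
      ev <- evaluate_model(model, folds[[f + 1L]]$test)
      per_run <- rbind(per_run, data.frame(
        repeat_ = r, fold = f, n = ev$n,
        accuracy = ev$accuracy, macro_f1 = ev$macro_f1,
        best_epoch = attr(model, "best_epoch")))
      cm_r <- if (is.null(cm_r)) ev$confusion else cm_r + ev$confusion
      per_class_acc <- if (is.null(per_class_acc)) ev$per_class[, -1L] else
        per_class_acc + ev$per_class[, -1L]
      confusion <- if (is.null(confusion)) ev$confusion else
        confusion + ev$confusion
    }
    pm <- metrics_from_confusion(cm_r)
    pooled <- rbind(pooled, data.frame(repeat_ = r, accuracy = pm$accuracy,
                                       macro_f1 = pm$macro_f1))
  }
  fold_sizes <- per_run$n[per_run$repeat_ == 0]
  aggregate <- list(
    accuracy_mean = mean(per_run$accuracy),
    accuracy_sd = stats::sd(per_run$accuracy),
    macro_f1_mean = mean(per_run$macro_f1),
    macro_f1_sd = stats::sd(per_run$macro_f1),
    accuracy_weighted = sum(per_run$accuracy * per_run$n) / sum(per_run$n),
    pooled_accuracy_mean = mean(pooled$accuracy),
    pooled_macro_f1_mean = mean(pooled$macro_f1)
  )
  per_class <- cbind(class = seq_len(model_config$n_classes),
                     per_class_acc / nrow(per_run))
  structure(list(per_run = per_run, pooled = pooled, aggregate = aggregate,
                 confusion = confusion, per_class = per_class, oov = oov,
                 fold_assignment = fa, fold_sizes = fold_sizes,
                 model = if (model_config$use_char) "BILSTM+ATT+CHAR" else
                   "BILSTM+ATT"),
            class = "hf_eval_report")
}

#' @export
print.hf_eval_report <- function(x, ...) {
  cat(sprintf("<hf_eval_report> %s: %d repeat(s) x %d fold(s)\n",
              x$model, length(unique(x$per_run$repeat_)),
              length(unique(x$per_run$fold))))
  cat(sprintf("  accuracy  %.2f%% (sd %.2f), macro-F1 %.2f%% (sd %.2f)\n",
              x$aggregate$accuracy_mean, x$aggregate$accuracy_sd %||% NA,
              x$aggregate$macro_f1_mean, x$aggregate$macro_f1_sd %||% NA))
  cat(sprintf("  pooled-confusion aggregation: accuracy %.2f%%, macro-F1 %.2f%%\n",
              x$aggregate$pooled_accuracy_mean, x$aggregate$pooled_macro_f1_mean))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param x an `hf_eval_report`.
#' @param path destination JSON file.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "hf_eval_report"))
  out <- list(model = x$model, per_run = x$per_run, pooled = x$pooled,
              aggregate = x$aggregate,
              confusion = as.data.frame(unclass(x$confusion)),
              per_class = x$per_class,
              oov = unclass(x$oov))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
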