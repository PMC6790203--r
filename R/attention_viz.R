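# Attention-map export (per-token weights rendered as color intensity) and
# out-of-vocabulary probability probes comparing the word-only and
# character-augmented model variants.

#' Attention map for one message
#'
#' Extracts the attention weights from a forward pass: one weight per
#' token, summing to 1, exposing which words the model attended to for its
#' class decision.
#'
#' @param tweet an `hf_tokens` object (or character vector of tokens).
#' @param model a trained [init_params()] object.
#' @return object of class `hf_attention_map`: `tokens`, `weights`,
#'   `predicted`, `true` (NA when unlabeled).
#' @export
attention_map <- function(tweet, model) {
  fw <- predict_tweet(tweet, model)
  true <- if (inherits(tweet, "hf_tokens")) tweet$label else NA_integer_
  structure(list(tokens = fw$tokens, weights = fw$alpha,
                 predicted = fw$predicted, true = true),
            class = "hf_attention_map")
}

#' @export
print.hf_attention_map <- function(x, ...) {
  cat(sprintf("<hf_attention_map> predicted class %d%s\n", x$predicted,
              if (!is.na(x$true)) sprintf(" (true %d)", x$true) else ""))
  cat(" ", paste(sprintf("%s[%.2f]", x$tokens, x$weights), collapse = " "), "\n")
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Render attention maps as standalone HTML
#'
#' Each token is drawn with a background whose opacity is proportional to
#' its attention weight, normalized per message by the maximum weight (so
#' the most-attended token always has full intensity). Output is
#' deterministic for fixed input.
#'
#' @param maps list of [attention_map()] objects.
#' @param path destination HTML file.
#' @return `path`, invisibly.
#' @export
render_html <- function(maps, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: %s", dir)
  head <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>Attention maps</title>",
    "<style>",
    "body { font-family: sans-serif; margin: 2em; }",
    ".tweet { margin: 0.6em 0; line-height: 1.9; }",
    ".tok { padding: 0.15em 0.25em; border-radius: 3px; }",
    ".meta { color: #666; font-size: 0.85em; margin-right: 0.8em; }",
    "</style></head><body>",
    "<h1>Attention maps</h1>")
  rows <- vapply(maps, function(m) {
    wmax <- max(m$weights)
    intensity <- if (wmax > 0) m$weights / wmax else rep(0, length(m$weights))
    spans <- sprintf(
      "<span class=\"tok\" style=\"background: rgba(217,72,47,%.3f)\" title=\"%.4f\">%s</span>",
      intensity, m$weights, html_escape(m$tokens))
    meta <- sprintf("pred %d%s", m$predicted,
                    if (!is.na(m$true)) sprintf(", true %d", m$true) else "")
    sprintf("<div class=\"tweet\"><span class=\"meta\">%s</span>%s</div>",
            meta, paste(spans, collapse = " "))
  }, character(1))
  writeLines(c(head, rows, "</body></html>"), path, useBytes = TRUE)
  invisible(path)
}

#' Out-of-vocabulary probability probe
#'
#' For each labeled message, flags its out-of-vocabulary tokens against a
#' vocabulary and reports the probability assigned to the true class by
#' two models — typically the word-only variant (A) and the
#' character-augmented variant (B) trained on the same folds — exposing
#' the confidence gain the character pathway brings on misspelled input.
#'
#' @param tokens an `hf_token_corpus` (unlabeled messages are skipped with
#'   a warning).
#' @param model_a,model_b trained [init_params()] objects.
#' @param vocab the [build_vocabulary()] the models were trained with;
#'   defaults to `model_a$vocab`.
#' @return data frame of class `hf_oov_probe`: id, true label, flagged OOV
#'   tokens (comma-joined), `n_oov`, `prob_a`, `prob_b`.
#' @export
oov_probe <- function(tokens, model_a, model_b, vocab = model_a$vocab) {
  labels <- token_labels(tokens)
  if (anyNA(labels)) {
    warning(sprintf("%d unlabeled message(s) skipped in oov_probe",
                    sum(is.na(labels))), call. = FALSE)
    tokens <- tokens[!is.na(labels)]
    labels <- labels[!is.na(labels)]
  }
  known <- known_entries(vocab$word_index)
  rows <- lapply(seq_along(tokens), function(i) {
    t <- tokens[[i]]
    oov <- unique(t$tokens[!(t$tokens %in% known)])
    pa <- predict_tweet(t, model_a)$probabilities[labels[i]]
    pb <- predict_tweet(t, model_b)$probabilities[labels[i]]
    data.frame(id = t$id, true = labels[i],
               oov_tokens = paste(oov, collapse = ","),
               n_oov = length(oov), prob_a = pa, prob_b = pb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hf_oov_probe", "data.frame")
  out
}
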