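# Word and character vocabularies built from training folds, and
# out-of-vocabulary (OOV) auditing across test folds.

PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"
PAD_INDEX <- 0L
UNK_INDEX <- 1L

#' Build word and character vocabularies from training messages
#'
#' Index 0 is reserved for padding and index 1 for the unknown symbol in
#' both maps. Words with training frequency below `min_count` are not
#' indexed (they map to the unknown symbol); every character occurring in
#' any training word is indexed regardless of `min_count`. Index order is
#' deterministic: frequency descending, ties broken lexicographically.
#'
#' @param tokens an `hf_token_corpus` (or list of `hf_tokens`) from the
#'   training part only.
#' @param min_count minimum word frequency to be indexed (default 1: no
#'   pruning).
#' @return object of class `hf_vocabulary`: list with `word_index` and
#'   `char_index`, both named integer vectors with 0-based contiguous
#'   indices including the reserved symbols.
#' @export
build_vocabulary <- function(tokens, min_count = 1L) {
  if (length(tokens) == 0L) stop_validation("cannot build vocabulary from empty input")
  if (!is_count(min_count, min = 1L)) stop_validation("min_count must be >= 1")
  words <- unlist(lapply(tokens, function(t) t$tokens), use.names = FALSE)
  if (length(words) == 0L) stop_validation("no tokens in training input")
  wt <- table(words)
  ord <- order(-as.integer(wt), names(wt), method = "radix")
  kept <- names(wt)[ord][as.integer(wt)[ord] >= min_count]
  word_index <- stats::setNames(
    seq_along(kept) + 1L,  # 0 = PAD, 1 = UNK
    kept)
  word_index <- c(stats::setNames(c(PAD_INDEX, UNK_INDEX),
                                  c(PAD_TOKEN, UNK_TOKEN)), word_index)
  chars <- unlist(strsplit(names(wt), "", fixed = TRUE), use.names = FALSE)
  # weight characters by word frequency so ordering reflects corpus usage
  chfreq <- tapply(
    rep(as.integer(wt), nchar(names(wt))), chars, sum)
  cord <- order(-as.integer(chfreq), names(chfreq), method = "radix")
  char_index <- stats::setNames(seq_along(chfreq) + 1L, names(chfreq)[cord])
  char_index <- c(stats::setNames(c(PAD_INDEX, UNK_INDEX),
                                  c(PAD_TOKEN, UNK_TOKEN)), char_index)
  structure(list(word_index = word_index, char_index = char_index,
                 min_count = as.integer(min_count)),
            class = "hf_vocabulary")
}

#' @export
print.hf_vocabulary <- function(x, ...) {
  cat(sprintf("<hf_vocabulary> %d word(s), %d character(s) (incl. pad/unk)\n",
              length(x$word_index), length(x$char_index)))
  invisible(x)
}

# Known (non-reserved) entries of an index map.
known_entries <- function(index) {
  setdiff(names(index), c(PAD_TOKEN, UNK_TOKEN))
}

#' Out-of-vocabulary rate of a test set against a vocabulary
#'
#' The percentage of test-side units absent from the corresponding index.
#' With `level = "token"` (default) every occurrence counts; with
#' `level = "type"` each distinct unit counts once. The reserved padding
#' and unknown symbols never count as known matches.
#'
#' @param vocab an [build_vocabulary()] result.
#' @param tokens test messages (`hf_token_corpus` or list of `hf_tokens`).
#' @param unit `"word"` for word tokens, `"char"` for character occurrences
#'   within word tokens.
#' @param level `"token"` (occurrences) or `"type"` (distinct units).
#' @return percentage in \[0, 100\].
#' @export
#' @examples
#' \dontrun{
#' oov_rate(vocab, test_tokens, unit = "word")
#' }
oov_rate <- function(vocab, tokens, unit = c("word", "char"),
                     level = c("token", "type")) {
  stopifnot(inherits(vocab, "hf_vocabulary"))
  unit <- match.arg(unit)
  level <- match.arg(level)
  words <- unlist(lapply(tokens, function(t) t$tokens), use.names = FALSE)
  if (length(words) == 0L) stop_validation("empty test set in oov_rate")
  units <- if (unit == "word") {
    words
  } else {
    unlist(strsplit(words, "", fixed = TRUE), use.names = FALSE)
  }
  if (level == "type") units <- unique(units)
  index <- if (unit == "word") vocab$word_index else vocab$char_index
  known <- units %in% known_entries(index)
  100 * mean(!known)
}

#' Assemble an OOV report from per-fold rates
#'
#' The aggregator behind [oov_report()]: takes per-fold word and character
#' OOV percentages and computes their arithmetic-mean averages. Averages
#' are kept unrounded internally; the print method displays them half-up
#' rounded to 2 decimals.
#'
#' @param word_rates numeric vector of per-fold word OOV percentages.
#' @param char_rates numeric vector of per-fold character OOV percentages
#'   (same length).
#' @return object of class `hf_oov_report`.
#' @export
#' @examples
#' rep <- oov_report_from_rates(c(8.64, 8.52, 9.26), c(0.07, 0.07, 0.03))
#' rep$word_average
oov_report_from_rates <- function(word_rates, char_rates = rep(NA_real_, length(word_rates))) {
  stopifnot(length(word_rates) == length(char_rates))
  if (any(!is.na(word_rates) & (word_rates < 0 | word_rates > 100))) {
    stop_validation("OOV rates must lie in [0, 100]")
  }
  structure(list(per_fold_word_rate = as.numeric(word_rates),
                 per_fold_char_rate = as.numeric(char_rates),
                 word_average = mean(word_rates),
                 char_average = mean(char_rates)),
            class = "hf_oov_report")
}

#' Per-fold OOV audit over a cross-validation split
#'
#' For each fold, builds a vocabulary from the training part and measures
#' word- and character-level OOV rates on the test part, then averages.
#'
#' @param folds list of `list(train = , test = )` pairs of token corpora.
#' @param expected_folds number of folds the protocol expects (default 10);
#'   a different fold count is an error unless `expected_folds` is set to
#'   match (tests and reduced runs may override).
#' @param min_count passed to [build_vocabulary()].
#' @param level passed to [oov_rate()].
#' @return object of class `hf_oov_report` (see [oov_report_from_rates()]).
#' @export
oov_report <- function(folds, expected_folds = 10L, min_count = 1L,
                       level = c("token", "type")) {
  level <- match.arg(level)
  if (length(folds) != expected_folds) {
    stop_validation("expected %d folds, got %d", expected_folds, length(folds))
  }
  word <- numeric(length(folds))
  char <- numeric(length(folds))
  for (i in seq_along(folds)) {
    vocab <- build_vocabulary(folds[[i]]$train, min_count = min_count)
    word[i] <- oov_rate(vocab, folds[[i]]$test, unit = "word", level = level)
    char[i] <- oov_rate(vocab, folds[[i]]$test, unit = "char", level = level)
  }
  oov_report_from_rates(word, char)
}

#' @export
print.hf_oov_report <- function(x, ...) {
  cat("<hf_oov_report>\n")
  cat("  per-fold word OOV %:",
      paste(sprintf("%.2f", round_half_up(x$per_fold_word_rate, 2)), collapse = " "), "\n")
  if (!anyNA(x$per_fold_char_rate)) {
    cat("  per-fold char OOV %:",
        paste(sprintf("%.2f", round_half_up(x$per_fold_char_rate, 2)), collapse = " "), "\n")
  }
  cat(sprintf("  averages: word %.2f%%, char %s\n",
              round_half_up(x$word_average, 2),
              if (is.na(x$char_average)) "NA" else
                sprintf("%.2f%%", round_half_up(x$char_average, 2))))
  invisible(x)
}

#' Serialize an OOV report to JSON
#'
#' @param x an `hf_oov_report`.
#' @param path destination JSON file.
#' @export
write_oov_report <- function(x, path) {
  stopifnot(inherits(x, "hf_oov_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
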