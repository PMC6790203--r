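# Deduplication and Twitter-aware normalization of raw messages into token
# sequences.
#
# Tokenizer rules (documented contract):
#   * URLs (http(s)://... or www....) are recognized as single tokens and
#     dropped.
#   * user mentions (@name) are recognized and dropped.
#   * hashtags are kept as their word content ("#saltlamp" -> "saltlamp").
#   * common western emoticons (":-)", ":D", ";p", ...) are kept as single
#     tokens.
#   * words may contain internal apostrophes ("i've" stays one token).
#   * everything else that contains no letter or digit is a pure-punctuation
#     token and is dropped.
#   * surviving tokens are lowercased, filtered against the stopword list,
#     and character runs longer than `max_repeat` are capped.

RE_URL <- "https?://[^[:space:]]+|www\\.[^[:space:]]+"
RE_MENTION <- "@[A-Za-z0-9_]+"
RE_HASHTAG <- "#[A-Za-z0-9_]+"
RE_EMOTICON <- "[:;=8Xx][-o^*']?[)(\\]\\[dDpP/\\\\|3oO]|<3|</3"
RE_WORD <- "[A-Za-z0-9_]+(?:['’][A-Za-z]+)*"
RE_PUNCT <- "[^A-Za-z0-9_[:space:]]+"

TOKEN_PATTERN <- paste(RE_URL, RE_MENTION, RE_HASHTAG, RE_EMOTICON,
                       RE_WORD, RE_PUNCT, sep = "|")

#' Default English stopword list
#'
#' The list bundled with the package (a standard Snowball-style English list
#' extended with common contractions). Token-level results depend on this
#' list, so it is shipped as a versioned data file rather than taken from an
#' external library.
#'
#' @return character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "hayfever")
  if (!nzchar(path)) stop_io("bundled stopword list not found")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Preprocessing configuration
#'
#' @param stopwords character vector of lowercase stopwords to remove.
#' @param retweet_markers prefixes (matched case-insensitively against the
#'   raw text) identifying retweets.
#' @param max_repeat cap on within-token character runs (default 3: a run
#'   of 3 like "aaahhh" survives, "soooooo" becomes "sooo").
#' @return object of class `hf_preprocess_config`.
#' @export
preprocess_config <- function(stopwords = default_stopwords(),
                              retweet_markers = c("RT "),
                              max_repeat = 3L) {
  if (!is_count(max_repeat, min = 1L)) stop_validation("max_repeat must be >= 1")
  structure(list(stopwords = tolower(stopwords),
                 retweet_markers = retweet_markers,
                 max_repeat = as.integer(max_repeat)),
            class = "hf_preprocess_config")
}

#' Remove retweets and duplicate messages
#'
#' Drops messages whose raw text starts with a retweet marker, then among
#' messages with byte-identical text (after Unicode NFC normalization) keeps
#' only the first occurrence. Relative order is preserved. Near-duplicates
#' are kept.
#'
#' @param x an [corpus()] object.
#' @param config an [preprocess_config()].
#' @return the filtered corpus, with attributes `n_retweets` and
#'   `n_duplicates` recording how many messages each rule removed.
#' @export
drop_retweets_and_duplicates <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "hf_corpus"))
  if (nrow(x) == 0L) {
    attr(x, "n_retweets") <- 0L
    attr(x, "n_duplicates") <- 0L
    return(x)
  }
  low <- tolower(x$text)
  is_rt <- rep(FALSE, nrow(x))
  for (m in config$retweet_markers) {
    is_rt <- is_rt | startsWith(low, tolower(m))
  }
  kept <- x[!is_rt, , drop = FALSE]
  norm <- stringi::stri_trans_nfc(kept$text)
  dup <- duplicated(norm)
  out <- kept[!dup, , drop = FALSE]
  class(out) <- c("hf_corpus", "data.frame")
  attr(out, "provenance") <- attr(x, "provenance")
  attr(out, "n_retweets") <- sum(is_rt)
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Cap character runs within a token
#'
#' Any maximal run of a single character longer than `max_repeat` is
#' shortened to exactly `max_repeat` characters; runs of length
#' `max_repeat` or less are untouched.
#'
#' @param token character vector of tokens.
#' @param max_repeat run cap (default 3).
#' @return character vector of normalized tokens.
#' @export
#' @examples
#' collapse_repeats(c("aaahhh", "soooooo", "cat"))  # "aaahhh" "sooo" "cat"
collapse_repeats <- function(token, max_repeat = 3L) {
  if (!is_count(max_repeat, min = 1L)) stop_validation("max_repeat must be >= 1")
  pattern <- sprintf("(.)\\1{%d,}", max_repeat)
  replacement <- paste(rep("\\1", max_repeat), collapse = "")
  gsub(pattern, replacement, token, perl = TRUE)
}

# Raw tokenization: returns all matched tokens of TOKEN_PATTERN in order.
raw_tokens <- function(text) {
  m <- gregexpr(TOKEN_PATTERN, text, perl = TRUE)
  regmatches(text, m)[[1]]
}

#' Tokenize and normalize one message
#'
#' Applies, in order: Twitter-aware tokenization; removal of URL and mention
#' tokens; hashtag unwrapping; lowercasing; removal of pure-punctuation
#' tokens; stopword removal; character-run capping via [collapse_repeats()].
#'
#' @param tweet a single-row [corpus()] slice, or a list with `id`, `text`
#'   and optional `label`.
#' @param config an [preprocess_config()].
#' @return a `hf_tokens` list: `id`, `tokens` (character vector), `label`.
#'   Messages whose every token is removed come back with zero tokens and
#'   attribute `empty = TRUE` (with a warning); they must be excluded from
#'   model input.
#' @export
tokenize_and_normalize <- function(tweet, config = preprocess_config()) {
  if (inherits(tweet, "hf_corpus")) {
    stopifnot(nrow(tweet) == 1L)
    tweet <- list(id = tweet$id[1], text = tweet$text[1], label = tweet$label[1])
  }
  toks <- raw_tokens(tweet$text %||% "")
  if (length(toks) > 0L) {
    is_url <- grepl(paste0("^(?:", RE_URL, ")$"), toks, perl = TRUE)
    is_mention <- grepl(paste0("^(?:", RE_MENTION, ")$"), toks, perl = TRUE)
    toks <- toks[!is_url & !is_mention]
    toks <- sub("^#", "", toks)
    toks <- tolower(toks)
    has_content <- grepl("[a-z0-9]", toks) |
      grepl(paste0("^(?:", RE_EMOTICON, ")$"), toks, perl = TRUE)
    toks <- toks[has_content]
    toks <- toks[!(toks %in% config$stopwords)]
    toks <- collapse_repeats(toks, config$max_repeat)
    toks <- toks[nzchar(toks)]
  }
  out <- structure(list(id = as.character(tweet$id %||% ""),
                        tokens = toks,
                        label = if (is.null(tweet$label)) NA_integer_ else
                          as.integer(tweet$label)),
                   class = "hf_tokens")
  if (length(toks) == 0L) {
    attr(out, "empty") <- TRUE
    warning(sprintf("message '%s' has no tokens after preprocessing", out$id),
            call. = FALSE)
  }
  out
}

#' Preprocess a whole corpus
#'
#' Composes [drop_retweets_and_duplicates()] with [tokenize_and_normalize()]
#' and removes messages that end up with no tokens. A summary of how many
#' messages each stage removed is attached as attribute `summary` and
#' reported via `message()` when `verbose = TRUE`.
#'
#' @param x an [corpus()] object.
#' @param config an [preprocess_config()].
#' @param verbose emit a per-stage summary message.
#' @return an object of class `hf_token_corpus`: list of `hf_tokens`.
#' @export
preprocess_corpus <- function(x, config = preprocess_config(), verbose = FALSE) {
  stopifnot(inherits(x, "hf_corpus"))
  filtered <- drop_retweets_and_duplicates(x, config)
  toks <- withCallingHandlers(
    lapply(seq_len(nrow(filtered)), function(i) {
      tokenize_and_normalize(filtered[i, , drop = FALSE], config)
    }),
    warning = function(w) invokeRestart("muffleWarning")
  )
  empty <- vapply(toks, function(t) isTRUE(attr(t, "empty")), logical(1))
  out <- toks[!empty]
  summary <- list(n_input = nrow(x),
                  n_retweets = attr(filtered, "n_retweets"),
                  n_duplicates = attr(filtered, "n_duplicates"),
                  n_empty = sum(empty),
                  n_output = length(out))
  if (verbose) {
    message(sprintf(
      "preprocess: %d in; removed %d retweet(s), %d duplicate(s), %d empty; %d out",
      summary$n_input, summary$n_retweets, summary$n_duplicates,
      summary$n_empty, summary$n_output))
  }
  structure(out, class = "hf_token_corpus", summary = summary)
}

#' @export
print.hf_token_corpus <- function(x, ...) {
  cat(sprintf("<hf_token_corpus> %d tokenized message(s)\n", length(x)))
  invisible(x)
}

#' @export
`[.hf_token_corpus` <- function(x, i) {
  structure(unclass(x)[i], class = "hf_token_corpus")
}

# Labels of a token corpus as an integer vector.
token_labels <- function(tokens) {
  vapply(tokens, function(t) t$label %||% NA_integer_, integer(1))
}

#' Write / read tokenized corpora as JSON-lines
#'
#' One object per line with keys `id`, `tokens`, and `label` (when present).
#'
#' @param tokens an `hf_token_corpus`.
#' @param path destination file.
#' @export
write_tokens <- function(tokens, path) {
  lines <- vapply(tokens, function(t) {
    rec <- list(id = t$id, tokens = t$tokens)
    if (!is.na(t$label)) rec$label <- t$label
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tokens
#' @export
read_tokens <- function(path) {
  if (!file.exists(path)) stop_io("token file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    structure(list(id = as.character(r$id),
                   tokens = as.character(r$tokens),
                   label = if (is.null(r$label)) NA_integer_ else as.integer(r$label)),
              class = "hf_tokens")
  })
  structure(out, class = "hf_token_corpus")
}
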