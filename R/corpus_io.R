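# Reading and writing labeled corpora, pretrained embedding tables, fold
# assignments and prediction tables in plain-text formats.

VALID_LABELS <- 1:4

#' Construct a labeled corpus
#'
#' A corpus is an ordered collection of short messages, each with a unique
#' string id, raw text, and an optional relevance label in 1..4 (1 = most
#' relevant personal reporting, 4 = unrelated/ambiguous).
#'
#' @param id character vector of unique identifiers.
#' @param text character vector of raw message text.
#' @param label integer labels in `1:4`, or `NA` for unlabeled messages.
#' @param provenance free-text note on where the corpus came from.
#' @return an object of class `hf_corpus`: a data frame with columns
#'   `id`, `text`, `label`.
#' @export
#' @examples
#' corpus(c("a", "b"), c("hay fever again", "pollen count high"), c(2L, 3L))
corpus <- function(id, text, label = NA_integer_, provenance = "") {
  id <- as.character(id)
  text <- as.character(text)
  n <- length(id)
  if (length(text) != n) stop_validation("id and text lengths differ")
  label <- suppressWarnings(as.integer(label))
  label <- rep_len(label, max(n, 1L))[seq_len(n)]
  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    stop_validation("duplicate id(s) in corpus: %s",
                    paste(utils::head(unique(dup), 5L), collapse = ", "))
  }
  bad <- !is.na(label) & !(label %in% VALID_LABELS)
  if (any(bad)) {
    stop_validation("label outside {1,2,3,4} for id(s): %s",
                    paste(utils::head(id[bad], 5L), collapse = ", "))
  }
  out <- data.frame(id = id, text = text, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("hf_corpus", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.hf_corpus <- function(x, ...) {
  lab <- x$label[!is.na(x$label)]
  cat(sprintf("<hf_corpus> %d message(s), %d labeled\n", nrow(x), length(lab)))
  if (length(lab) > 0L) {
    cnt <- tabulate(lab, nbins = 4L)
    cat(sprintf("  class counts: %s\n",
                paste(sprintf("%d:%d", 1:4, cnt), collapse = " ")))
  }
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("  provenance:", attr(x, "provenance"), "\n")
  }
  invisible(x)
}

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("csv", "tsv", "jsonl")))
  switch(tolower(tools::file_ext(path)),
         csv = "csv", tsv = "tsv", tab = "tsv",
         jsonl = "jsonl", ndjson = "jsonl", json = "jsonl",
         stop_format("cannot infer corpus format from extension of '%s'", path))
}

#' Read a labeled corpus from disk
#'
#' Supported formats: `csv` and `tsv` with a header row containing at least
#' `id` and `text` (and optionally `label`), and `jsonl` with one JSON object
#' per line carrying the same keys. Labels must be integers in 1..4.
#'
#' @param path file to read.
#' @param format one of `"csv"`, `"tsv"`, `"jsonl"`; inferred from the file
#'   extension when omitted.
#' @return an [corpus()] object, record order preserved.
#' @export
read_corpus <- function(path, format = NULL) {
  if (!file.exists(path)) stop_io("corpus file not found: %s", path)
  format <- infer_format(path, format)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    if (length(recs) == 0L) return(corpus(character(), character()))
    ok <- vapply(recs, function(r) all(c("id", "text") %in% names(r)), logical(1))
    if (!all(ok)) {
      stop_format("jsonl line %d lacks required keys id/text", which(!ok)[1])
    }
    df <- data.frame(
      id = vapply(recs, function(r) as.character(r$id), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      label = vapply(recs, function(r) {
        if (is.null(r$label) || is.na(r$label)) NA_real_ else as.numeric(r$label)
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            colClasses = "character", comment.char = "",
                            fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (!all(c("id", "text") %in% names(df))) {
      stop_format("corpus file %s lacks required column(s): %s", path,
                  paste(setdiff(c("id", "text"), names(df)), collapse = ", "))
    }
    if (!"label" %in% names(df)) df$label <- NA_character_
    df$label <- suppressWarnings(as.numeric(df$label))
  }
  bad <- !is.na(df$label) & (df$label != round(df$label) | !(df$label %in% VALID_LABELS))
  if (any(bad)) {
    stop_validation("label outside {1,2,3,4} for id(s): %s",
                    paste(utils::head(df$id[bad], 5L), collapse = ", "))
  }
  corpus(df$id, df$text, as.integer(df$label),
         provenance = sprintf("read from %s (%s)", path, format))
}

#' Write a corpus to disk
#'
#' Text fields are quoted/escaped so embedded delimiters and newlines survive
#' a read/write round trip. Unlabeled messages get an empty `label` field
#' (csv/tsv) or no `label` key (jsonl).
#'
#' @param x an [corpus()] object.
#' @param path destination file.
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "hf_corpus"))
  format <- infer_format(path, format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: %s", dir)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      rec <- list(id = x$id[i], text = x$text[i])
      if (!is.na(x$label[i])) rec$label <- x$label[i]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(id = x$id, text = x$text,
                     label = ifelse(is.na(x$label), "", as.character(x$label)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = TRUE, qmethod = "double",
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read pretrained word vectors in text format
#'
#' Parses the whitespace-delimited text vector format used to distribute
#' GloVe and word2vec embeddings: one token followed by `d` floats per line.
#' A first line consisting of exactly two integer fields is auto-detected as
#' a count/dimension header and skipped, so both common dialects parse
#' identically.
#'
#' @param path file to read.
#' @return an object of class `hf_embedding_table`: list with `dimension`
#'   and `vectors` (a numeric matrix with one row per token, tokens as
#'   rownames).
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop_io("embedding file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format("embedding file %s is empty", path)
  first <- strsplit(trimws(lines[[1]]), "[ \t]+")[[1]]
  offset <- 0L
  if (length(first) == 2L && !anyNA(suppressWarnings(as.integer(first))) &&
      all(grepl("^[0-9]+$", first))) {
    offset <- 1L
    lines <- lines[-1L]
    if (length(lines) == 0L) stop_format("embedding file %s has only a header", path)
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  dim0 <- length(parts[[1]]) - 1L
  if (dim0 < 1L) stop_format("line %d: no vector fields", offset + 1L)
  nf <- lengths(parts)
  bad <- which(nf != dim0 + 1L)
  if (length(bad) > 0L) {
    stop_format("line %d: expected %d fields, found %d",
                offset + bad[1], dim0 + 1L, nf[bad[1]])
  }
  tokens <- vapply(parts, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim0))
  )
  if (anyNA(vals)) {
    bad <- which(apply(if (is.matrix(vals)) is.na(vals) else matrix(is.na(vals), nrow = 1), 2, any))[1]
    stop_format("line %d: non-numeric vector field", offset + bad)
  }
  mat <- t(matrix(vals, nrow = dim0))
  rownames(mat) <- tokens
  structure(list(dimension = dim0, vectors = mat),
            class = "hf_embedding_table")
}

#' @export
print.hf_embedding_table <- function(x, ...) {
  cat(sprintf("<hf_embedding_table> %d token(s), dimension %d\n",
              nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Per-class message counts
#'
#' @param x a fully labeled [corpus()] object.
#' @return list with `counts` (named vector over classes 1..4) and `total`.
#' @export
#' @examples
#' cc <- class_counts(corpus(letters[1:3], rep("hay fever", 3), c(1L, 1L, 3L)))
#' cc$total
class_counts <- function(x) {
  stopifnot(inherits(x, "hf_corpus"))
  if (anyNA(x$label)) {
    stop_validation("class_counts requires a fully labeled corpus (%d unlabeled)",
                    sum(is.na(x$label)))
  }
  counts <- tabulate(x$label, nbins = 4L)
  names(counts) <- as.character(1:4)
  list(counts = counts, total = sum(counts))
}

#' Write / read fold assignments
#'
#' Fold assignments are stored as a JSON object mapping message id to fold
#' index (0-based).
#'
#' @param assignment named integer vector (names = ids, values = folds).
#' @param path JSON file.
#' @return `read_fold_assignment` returns the named integer vector.
#' @export
write_fold_assignment <- function(assignment, path) {
  jsonlite::write_json(as.list(as.integer(assignment)) |>
                         stats::setNames(names(assignment)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_assignment
#' @export
read_fold_assignment <- function(path) {
  if (!file.exists(path)) stop_io("fold assignment file not found: %s", path)
  x <- jsonlite::fromJSON(path)
  stats::setNames(as.integer(unlist(x)), names(x))
}

#' Write a prediction table
#'
#' @param ids character ids.
#' @param predicted integer predicted classes.
#' @param probabilities numeric matrix (one row per message, one column per
#'   class).
#' @param path destination TSV.
#' @export
write_predictions <- function(ids, predicted, probabilities, path) {
  stopifnot(length(ids) == length(predicted),
            nrow(probabilities) == length(ids))
  df <- data.frame(id = ids, predicted_label = as.integer(predicted),
                   stringsAsFactors = FALSE)
  for (k in seq_len(ncol(probabilities))) {
    df[[sprintf("p%d", k)]] <- probabilities[, k]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
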