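# End-to-end orchestration: preprocess -> synth/load -> cross-validate
# (both model variants) -> report -> visualize, with a reproducibility
# manifest.

#' Run the full classification pipeline
#'
#' Executes, in order: corpus acquisition (a provided corpus file or the
#' synthetic generator), preprocessing, stratified fold assignment,
#' cross-validation of both model variants (with and without the character
#' pathway), an OOV audit, attention-map rendering and an OOV probability
#' probe from a pair of single-fold models, and writes every artifact plus
#' a manifest (seeds, configurations, file checksums) to `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param corpus_path optional corpus file readable by [read_corpus()];
#'   when `NULL` a synthetic corpus is generated from `spec`.
#' @param spec an [synth_spec()] used when no corpus is given.
#' @param preprocess an [preprocess_config()].
#' @param train an [train_config()].
#' @param model an [model_config()] (the char-free variant is derived from
#'   it automatically).
#' @param embeddings_path optional pretrained vector file for
#'   [read_embeddings()].
#' @param n_viz number of test messages to render attention maps for.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(out_dir,
                         corpus_path = NULL,
                         spec = synth_spec(),
                         preprocess = preprocess_config(),
                         train = train_config(),
                         model = model_config(),
                         embeddings_path = NULL,
                         n_viz = 12L) {
  if (!is.null(corpus_path) && !file.exists(corpus_path)) {
    stop_io("corpus file not found: %s", corpus_path)
  }
  if (!is.null(embeddings_path) && !file.exists(embeddings_path)) {
    stop_io("embeddings file not found: %s", embeddings_path)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  raw <- stage("acquire", {
    if (is.null(corpus_path)) {
      sc <- generate_corpus(spec)
      paths$corpus <- file.path(out_dir, "corpus.tsv")
      write_synth_corpus(sc, paths$corpus)
      paths$annotations <- paste0(paths$corpus, ".annotations.json")
      sc$corpus
    } else {
      read_corpus(corpus_path)
    }
  })
  tokens <- stage("preprocess", preprocess_corpus(raw, preprocess))
  paths$tokens <- file.path(out_dir, "tokens.jsonl")
  write_tokens(tokens, paths$tokens)

  embeddings <- if (!is.null(embeddings_path)) {
    stage("embeddings", read_embeddings(embeddings_path))
  } else NULL

  fa <- stage("folds", stratified_folds(tokens, train$folds, seed = train$seed))
  paths$folds <- file.path(out_dir, "folds.json")
  write_fold_assignment(fa, paths$folds)

  cfg_char <- model
  cfg_word <- model_config(
    word_dim = model$word_dim, char_dim = model$char_dim,
    char_kernels = model$char_kernels, kernel_width = model$kernel_width,
    lstm_units = model$lstm_units, attn_dim = model$attn_dim,
    n_classes = model$n_classes, use_char = FALSE,
    max_seq_len = model$max_seq_len, max_word_len = model$max_word_len)

  report_char <- stage("cross_validate_char",
                       cross_validate(tokens, train, cfg_char, embeddings))
  report_word <- stage("cross_validate_word",
                       cross_validate(tokens, train, cfg_word, embeddings))
  paths$report_char <- file.path(out_dir, "eval_char.json")
  paths$report_word <- file.path(out_dir, "eval_word.json")
  write_eval_report(report_char, paths$report_char)
  write_eval_report(report_word, paths$report_word)
  paths$oov <- file.path(out_dir, "oov_report.json")
  write_oov_report(report_char$oov, paths$oov)

  viz <- stage("visualize", {
    fold_of <- unname(fa)
    tr <- tokens[fold_of != 0L]
    te <- tokens[fold_of == 0L]
    m_char <- train_fold(tr, train, cfg_char, embeddings, seed = train$seed)
    m_word <- train_fold(tr, train, cfg_word, embeddings, seed = train$seed)
    sel <- te[seq_len(min(n_viz, length(te)))]
    maps <- lapply(sel, attention_map, model = m_char)
    paths$attention_html <- file.path(out_dir, "attention.html")
    render_html(maps, paths$attention_html)
    probes <- oov_probe(te, m_word, m_char)
    paths$oov_probe <- file.path(out_dir, "oov_probe.json")
    jsonlite::write_json(probes, paths$oov_probe, dataframe = "rows",
                         digits = NA)
    paths$attention_json <- file.path(out_dir, "attention.json")
    jsonlite::write_json(lapply(maps, unclass), paths$attention_json,
                         auto_unbox = TRUE, digits = NA)
    invisible(NULL)
  })

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("hayfever")),
    seed = train$seed,
    synthetic = is.null(corpus_path),
    configs = list(
      train = unclass(train),
      model = unclass(model)[setdiff(names(model), "input_dim")],
      preprocess = list(n_stopwords = length(preprocess$stopwords),
                        retweet_markers = preprocess$retweet_markers,
                        max_repeat = preprocess$max_repeat),
      spec = if (is.null(corpus_path)) {
        unclass(spec)[setdiff(names(spec), "pools")]
      } else NULL),
    summary = list(
      n_messages = length(tokens),
      char = report_char$aggregate,
      word = report_word$aggregate,
      oov_word_average = report_char$oov$word_average,
      oov_char_average = report_char$oov$char_average),
    outputs = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$path <- manifest_path
  invisible(manifest)
}
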