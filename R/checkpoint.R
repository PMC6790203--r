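# Model checkpointing: a single JSON document holding the configuration,
# vocabulary, and every named parameter array. Stable, diffable, and
# re-loadable across sessions.

#' Save / load a model checkpoint
#'
#' The checkpoint is one JSON file with three top-level keys: `config`,
#' `vocab` (word and character index maps), and `params` (named numeric
#' arrays with their dimensions). Numbers are written at full precision,
#' so save/load round-trips reproduce predictions exactly.
#'
#' @param model an [init_params()] object.
#' @param path destination file.
#' @return `load_model` returns the restored `hf_model_params`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hf_model_params"))
  ser <- list(
    format = "hayfever-checkpoint-1",
    config = unclass(model$config),
    vocab = list(word_index = as.list(model$vocab$word_index),
                 char_index = as.list(model$vocab$char_index),
                 min_count = model$vocab$min_count),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: %s", path)
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(ser$format, "hayfever-checkpoint-1")) {
    stop_format("unrecognized checkpoint format in %s", path)
  }
  cfg <- ser$config
  config <- model_config(cfg$word_dim, cfg$char_dim, cfg$char_kernels,
                         cfg$kernel_width, cfg$lstm_units, cfg$attn_dim,
                         cfg$n_classes, cfg$use_char, cfg$max_seq_len,
                         cfg$max_word_len)
  vocab <- structure(list(
    word_index = stats::setNames(as.integer(unlist(ser$vocab$word_index)),
                                 names(ser$vocab$word_index)),
    char_index = stats::setNames(as.integer(unlist(ser$vocab$char_index)),
                                 names(ser$vocab$char_index)),
    min_count = as.integer(ser$vocab$min_count)),
    class = "hf_vocabulary")
  params <- lapply(ser$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else
      as.numeric(p$data)
  })
  structure(list(params = params, config = config, vocab = vocab),
            class = "hf_model_params")
}
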