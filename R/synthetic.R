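# Synthetic noisy-tweet generator: labeled pseudo-tweet corpora with the
# statistical structure of the real task — four classes with overlapping
# vocabulary, heavy class imbalance, and controllable out-of-vocabulary
# rates via spelling noise — so every other module is testable without any
# data download.

#' Default themed word pools
#'
#' Five pools bundled as plain-text data files: a shared pool of confusable
#' hay-fever terms that occur in every class (so classes overlap, the way
#' "sneeze" appears in both symptom reports and advertisements), and one
#' pool per class themed on the annotation schema — detailed symptom and
#' treatment reporting (class 1), generic personal reporting (class 2),
#' warnings/news/marketing (class 3), and unrelated/ambiguous chatter
#' (class 4).
#'
#' @return named list of character vectors: `shared`, `class1`..`class4`.
#' @export
default_word_pools <- function() {
  dir <- system.file("extdata", "pools", package = "hayfever")
  if (!nzchar(dir)) stop_io("bundled word pools not found")
  pools <- lapply(c(shared = "shared", class1 = "class1", class2 = "class2",
                    class3 = "class3", class4 = "class4"),
                  function(nm) readLines(file.path(dir, paste0(nm, ".txt")),
                                         encoding = "UTF-8", warn = FALSE))
  pools
}

#' Synthetic corpus specification
#'
#' Defaults reproduce the published study conditions: 3862 messages with
#' class proportions 719/1823/938/382, short token sequences, and spelling
#' noise calibrated so the 10-fold test-side word OOV rate is near 9% while
#' the character OOV rate stays near zero.
#'
#' @param n corpus size.
#' @param class_proportions four proportions summing to 1; class counts are
#'   made exact by largest-remainder rounding.
#' @param tweet_length integer min/max tokens per message (uniform).
#' @param class_mix probability that a token is drawn from the class pool
#'   rather than the shared pool.
#' @param noise_rates named per-token probabilities for the three noise
#'   operators: `stretch` (character-run stretching to the run cap),
#'   `swap` (adjacent-character transposition), `truncate`
#'   (abbreviation-style suffix truncation). These mirror the spelling,
#'   typo and abbreviation errors observed in user-generated text.
#' @param noise_chain probability that a perturbed token receives a second
#'   (compounding) perturbation. Compounding keeps the space of misspelled
#'   variants large relative to the corpus, so that perturbed forms stay
#'   rare enough to be out-of-vocabulary even in large corpora — as real
#'   misspellings do.
#' @param target_oov desired 10-fold average word OOV percentage, used by
#'   [calibrate_oov()].
#' @param seed integer seed; generation is deterministic given it.
#' @param pools word pools, as from [default_word_pools()].
#' @return object of class `hf_synth_spec`.
#' @export
synth_spec <- function(n = 3862L,
                       class_proportions = c(719, 1823, 938, 382) / 3862,
                       tweet_length = c(4L, 12L),
                       class_mix = 0.55,
                       noise_rates = c(stretch = 0.08, swap = 0.08,
                                       truncate = 0.08),
                       noise_chain = 0.5,
                       target_oov = 9,
                       seed = 20181L,
                       pools = default_word_pools()) {
  if (!is_count(n, 1L)) stop_validation("n must be a positive integer")
  if (length(class_proportions) != 4L ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    stop_validation("class_proportions must be 4 values summing to 1")
  }
  if (any(noise_rates < 0) || sum(noise_rates) > 1) {
    stop_validation("noise_rates must be non-negative and sum to <= 1")
  }
  if (noise_chain < 0 || noise_chain > 1) {
    stop_validation("noise_chain must lie in [0, 1]")
  }
  if (any(lengths(pools) == 0L)) stop_validation("empty word pool")
  structure(list(n = as.integer(n), class_proportions = class_proportions,
                 tweet_length = as.integer(tweet_length),
                 class_mix = class_mix,
                 noise_rates = noise_rates[c("stretch", "swap", "truncate")],
                 noise_chain = noise_chain,
                 target_oov = target_oov, seed = as.integer(seed),
                 pools = pools),
            class = "hf_synth_spec")
}

# Largest-remainder (Hamilton) apportionment of n into proportions.
largest_remainder <- function(n, proportions) {
  exact <- n * proportions
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0L) {
    rem <- exact - counts
    extra <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# Noise operators. Each returns the perturbed token, or the original when
# no distinct perturbation exists.
noise_stretch <- function(word, max_repeat = 3L) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), 1L)
  # stretch to a run of exactly max_repeat so the result is stable under
  # the preprocessing run cap
  paste0(paste(ch[seq_len(pos)], collapse = ""),
         strrep(ch[pos], max_repeat - 1L),
         if (pos < length(ch)) paste(ch[(pos + 1L):length(ch)], collapse = "") else "")
}

noise_swap <- function(word) {
  nc <- nchar(word)
  if (nc < 2L) return(word)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  pos <- sample.int(nc - 1L, 1L)
  tmp <- ch[pos]; ch[pos] <- ch[pos + 1L]; ch[pos + 1L] <- tmp
  paste(ch, collapse = "")
}

noise_truncate <- function(word) {
  nc <- nchar(word)
  keep <- max(3L, ceiling(nc * 0.6))
  if (keep >= nc) return(word)
  substr(word, 1L, keep)
}

#' Generate a synthetic labeled corpus
#'
#' Class counts are exact (largest-remainder rounding of the proportions).
#' Each message draws a uniform length, then tokens from a mixture of the
#' shared pool and its class pool, making classes separable but
#' overlapping. Noise operators then perturb tokens at the configured
#' per-token rates into misspelled variants absent from the clean pools
#' (perturbations that collide with a pool word are dropped). Generation is
#' deterministic under the spec seed, and every perturbation is recorded.
#'
#' @param spec an [synth_spec()].
#' @return object of class `hf_synth_corpus`: list with `corpus` (an
#'   [corpus()], text = space-joined tokens), `annotations` (data frame of
#'   perturbed tokens: id, position, original, token, op) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "hf_synth_spec"))
  pool_union <- unique(unlist(spec$pools, use.names = FALSE))
  counts <- largest_remainder(spec$n, spec$class_proportions)
  with_seed(spec$seed, {
    labels <- sample(rep(1:4, counts))
    ids <- sprintf("s%05d", seq_len(spec$n))
    texts <- character(spec$n)
    ann <- vector("list", spec$n)
    rates <- spec$noise_rates
    cum <- cumsum(rates)
    for (i in seq_len(spec$n)) {
      len <- sample(spec$tweet_length[1]:spec$tweet_length[2], 1L)
      cl_pool <- spec$pools[[paste0("class", labels[i])]]
      from_class <- stats::runif(len) < spec$class_mix
      toks <- ifelse(from_class,
                     sample(cl_pool, len, replace = TRUE),
                     sample(spec$pools$shared, len, replace = TRUE))
      u <- stats::runif(len)
      recs <- list()
      apply_op <- function(word, op) {
        switch(op,
               stretch = noise_stretch(word),
               swap = noise_swap(word),
               truncate = noise_truncate(word))
      }
      draw_op <- function() {
        v <- stats::runif(1) * cum[3]
        if (v < cum[1]) "stretch" else if (v < cum[2]) "swap" else "truncate"
      }
      for (j in seq_len(len)) {
        if (u[j] >= cum[3]) next
        op <- if (u[j] < cum[1]) "stretch" else if (u[j] < cum[2]) "swap" else "truncate"
        variant <- apply_op(toks[j], op)
        # compounding perturbation keeps the variant space large
        if (stats::runif(1) < spec$noise_chain %||% 0) {
          op2 <- draw_op()
          variant <- apply_op(variant, op2)
          op <- paste(op, op2, sep = "+")
        }
        # keep variants stable under the preprocessing run cap
        variant <- collapse_repeats(variant, 3L)
        if (variant == toks[j] || variant %in% pool_union) next
        recs[[length(recs) + 1L]] <- data.frame(
          id = ids[i], position = j, original = toks[j], token = variant,
          op = op, stringsAsFactors = FALSE)
        toks[j] <- variant
      }
      texts[i] <- paste(toks, collapse = " ")
      if (length(recs) > 0L) ann[[i]] <- do.call(rbind, recs)
    }
    annotations <- do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
    if (is.null(annotations)) {
      annotations <- data.frame(id = character(), position = integer(),
                                original = character(), token = character(),
                                op = character(), stringsAsFactors = FALSE)
    }
    structure(list(corpus = corpus(ids, texts, labels,
                                   provenance = "synthetic generator"),
                   annotations = annotations, spec = spec),
              class = "hf_synth_corpus")
  })
}

#' @export
print.hf_synth_corpus <- function(x, ...) {
  cat(sprintf("<hf_synth_corpus> %d message(s), %d perturbed token(s)\n",
              nrow(x$corpus), nrow(x$annotations)))
  invisible(x)
}

# Token corpus straight from generator output (tokens are already clean,
# lowercase, and run-capped, so splitting on spaces is exact).
synth_tokens <- function(sc) {
  stopifnot(inherits(sc, "hf_synth_corpus"))
  toks <- strsplit(sc$corpus$text, " ", fixed = TRUE)
  structure(Map(function(id, tt, lab) {
    structure(list(id = id, tokens = tt, label = lab), class = "hf_tokens")
  }, sc$corpus$id, toks, sc$corpus$label, USE.NAMES = FALSE),
  class = "hf_token_corpus")
}

# Measure the k-fold average word/char OOV of a spec's output.
measure_oov <- function(spec, folds = 10L) {
  sc <- generate_corpus(spec)
  tokens <- synth_tokens(sc)
  fa <- stratified_folds(tokens, folds, seed = spec$seed + 1L)
  fold_of <- unname(fa)
  fl <- lapply(0:(folds - 1L), function(f) {
    list(train = tokens[fold_of != f], test = tokens[fold_of == f])
  })
  oov_report(fl, expected_folds = folds)
}

#' Calibrate noise rates to a target OOV level
#'
#' Scales the three noise rates by a common multiplier, found by bisection,
#' so that the generated corpus's k-fold average word OOV rate lands within
#' `tol` percentage points of `spec$target_oov`. The character OOV rate of
#' the calibrated output stays near zero because noise only rearranges,
#' repeats or drops characters already present in training words.
#'
#' @param spec an [synth_spec()].
#' @param folds number of folds used for the OOV measurement.
#' @param tol acceptable deviation from the target, percentage points.
#' @param max_iter bisection iterations.
#' @return the spec with scaled `noise_rates`, with attributes
#'   `measured_word_oov` and `measured_char_oov`.
#' @export
calibrate_oov <- function(spec, folds = 10L, tol = 1, max_iter = 20L) {
  stopifnot(inherits(spec, "hf_synth_spec"))
  target <- spec$target_oov
  if (!(target > 0 && target < 100)) {
    stop_validation("target_oov must be in (0, 100)")
  }
  base <- spec$noise_rates
  if (sum(base) <= 0) stop_validation("noise_rates are all zero; nothing to calibrate")
  cap <- 0.95 / sum(base)  # keep total per-token noise probability < 0.95
  eval_mult <- function(mult) {
    sp <- spec
    sp$noise_rates <- base * mult
    rep <- measure_oov(sp, folds)
    list(spec = sp, word = rep$word_average, char = rep$char_average)
  }
  lo <- 0; hi <- 1
  r <- eval_mult(hi)
  while (r$word < target - tol && hi < cap) {
    hi <- min(cap, hi * 2)
    r <- eval_mult(hi)
  }
  if (r$word < target - tol) {
    stop_validation(paste0(
      "target OOV %.1f%% unreachable (measured %.2f%% at maximum noise); ",
      "use larger or more diverse word pools"), target, r$word)
  }
  best <- r
  best_mult <- hi
  for (it in seq_len(max_iter)) {
    if (abs(best$word - target) <= tol) break
    mid <- (lo + hi) / 2
    r <- eval_mult(mid)
    if (abs(r$word - target) < abs(best$word - target)) {
      best <- r
      best_mult <- mid
    }
    if (r$word < target) lo <- mid else hi <- mid
  }
  out <- best$spec
  attr(out, "measured_word_oov") <- best$word
  attr(out, "measured_char_oov") <- best$char
  attr(out, "noise_multiplier") <- best_mult
  out
}

#' Separability certificate for a synthetic corpus
#'
#' Scores a deliberately trivial frequency-based classifier — each token
#' votes for the class under which it is relatively most frequent, the
#' message takes the majority vote — against the majority-class baseline.
#' A vote accuracy above the baseline certifies that the corpus carries
#' learnable class signal.
#'
#' @param sc an [generate_corpus()] result.
#' @return list with `majority_accuracy`, `vote_accuracy` (percentages)
#'   and `n`.
#' @export
separability_check <- function(sc) {
  stopifnot(inherits(sc, "hf_synth_corpus"))
  tokens <- synth_tokens(sc)
  labels <- token_labels(tokens)
  n <- length(labels)
  # per-class relative token frequencies
  tok_by_class <- lapply(1:4, function(cl) {
    unlist(lapply(tokens[labels == cl], `[[`, "tokens"), use.names = FALSE)
  })
  vocab_all <- unique(unlist(tok_by_class, use.names = FALSE))
  freq <- sapply(tok_by_class, function(tt) {
    tab <- table(factor(tt, levels = vocab_all))
    as.numeric(tab) / max(1L, length(tt))
  })
  rownames(freq) <- vocab_all
  tok_class <- max.col(freq, ties.method = "first")
  names(tok_class) <- vocab_all
  votes <- vapply(tokens, function(t) {
    v <- tok_class[t$tokens]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(which.max(tabulate(labels, 4L)))
    tab <- tabulate(v, nbins = 4L)
    which.max(tab)
  }, integer(1))
  majority <- 100 * max(tabulate(labels, 4L)) / n
  vote_acc <- 100 * mean(votes == labels)
  list(majority_accuracy = majority, vote_accuracy = vote_acc, n = n)
}

#' Write a synthetic corpus with its noise-annotation sidecar
#'
#' @param sc an [generate_corpus()] result.
#' @param path corpus destination (format per [write_corpus()]).
#' @param annotation_path JSON sidecar for the noise annotations; default
#'   `<path>.annotations.json`.
#' @export
write_synth_corpus <- function(sc, path,
                               annotation_path = paste0(path, ".annotations.json")) {
  stopifnot(inherits(sc, "hf_synth_corpus"))
  write_corpus(sc$corpus, path)
  jsonlite::write_json(sc$annotations, annotation_path, dataframe = "rows")
  invisible(path)
}
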