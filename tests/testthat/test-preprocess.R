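test_that("retweets and exact duplicates are removed, order preserved", {
  x <- corpus(c("a", "b", "c", "d"),
              c("RT @x: hay fever", "hay fever bad", "hay fever bad",
                "pollen high"),
              c(1L, 2L, 2L, 3L))
  y <- drop_retweets_and_duplicates(x)
  expect_identical(y$text, c("hay fever bad", "pollen high"))
  expect_identical(attr(y, "n_retweets"), 1L)
  expect_identical(attr(y, "n_duplicates"), 1L)
  # all-distinct non-retweet corpus is untouched; empty corpus stays empty
  clean <- corpus(c("a", "b"), c("one msg", "two msg"), c(1L, 1L))
  expect_identical(drop_retweets_and_duplicates(clean)$text, clean$text)
  expect_identical(nrow(drop_retweets_and_duplicates(corpus(character(), character()))), 0L)
})

test_that("character runs are capped at max_repeat, matching an rle oracle", {
  expect_identical(collapse_repeats("aaahhh"), "aaahhh")  # runs of 3 survive
  expect_identical(collapse_repeats("soooooo"), "sooo")
  expect_identical(collapse_repeats("cat"), "cat")
  withr::with_seed(42, {
    for (i in 1:200) {
      tok <- paste(sample(letters[1:3], sample(1:12, 1), replace = TRUE),
                   collapse = "")
      cap <- sample(1:4, 1)
      expect_identical(collapse_repeats(tok, cap),
                       collapse_repeats_oracle(tok, cap))
    }
  })
})

test_that("tokenization lowercases and strips URLs, mentions, punctuation and stopwords", {
  cfg <- preprocess_config()
  t1 <- tokenize_and_normalize(list(id = "a", text = "probs hay fever"), cfg)
  expect_identical(t1$tokens, c("probs", "hay", "fever"))
  cfg2 <- preprocess_config(stopwords = c(default_stopwords(), "now"))
  t2 <- tokenize_and_normalize(
    list(id = "b", text = "Visit http://a.b now!!!"), cfg2)
  expect_identical(t2$tokens, "visit")
  t3 <- tokenize_and_normalize(
    list(id = "c", text = "@doc my EYES are watering!! #saltlamp https://x.y"), cfg)
  expect_identical(t3$tokens, c("eyes", "watering", "saltlamp"))
  expect_warning(t4 <- tokenize_and_normalize(list(id = "d", text = ""), cfg),
                 "no tokens")
  expect_true(isTRUE(attr(t4, "empty")))
})

test_that("corpus preprocessing composes the stages and drops empty messages", {
  cfg <- preprocess_config()
  x <- corpus(c("a", "b", "c", "d", "e"),
              c("RT @z: old news", "sneezing all morning", "sneezing all morning",
                "the of and", "pollen count HIGH today http://news.example"),
              c(1L, 1L, 1L, 4L, 3L))
  out <- preprocess_corpus(x, cfg)
  s <- attr(out, "summary")
  expect_identical(s$n_retweets, 1L)
  expect_identical(s$n_duplicates, 1L)
  expect_identical(s$n_empty, 1L)
  expect_identical(length(out), 2L)
  expect_identical(out[[2]]$tokens, c("pollen", "count", "high", "today"))
  expect_identical(out[[2]]$label, 3L)
})

test_that("preprocessing is idempotent and never grows token counts", {
  cfg <- preprocess_config()
  x <- corpus(sprintf("m%d", 1:6),
              c("My eyes are WATERING today!!", "soooooo much pollen :(",
                "hayfever meds not working", "@user check www.shop.example deals",
                "Sneezing #nonstop all week", "plain words only here"),
              rep(2L, 6))
  once <- preprocess_corpus(x, cfg)
  rebuilt <- corpus(vapply(once, `[[`, character(1), "id"),
                    vapply(once, function(t) paste(t$tokens, collapse = " "),
                           character(1)),
                    vapply(once, `[[`, integer(1), "label"))
  twice <- preprocess_corpus(rebuilt, cfg)
  expect_identical(lapply(twice, `[[`, "tokens"), lapply(once, `[[`, "tokens"))
  # per-message token counts never exceed raw whitespace token counts
  raw_counts <- lengths(strsplit(x$text, "[[:space:]]+"))
  for (t in once) {
    i <- match(t$id, x$id)
    expect_lte(length(t$tokens), raw_counts[i])
  }
})

test_that("no output token violates the URL, mention, stopword or run-cap rules", {
  cfg <- preprocess_config()
  corp <- random_token_corpus(25, seed = 9)
  x <- corpus(sprintf("r%d", 1:25),
              vapply(corp, function(t) {
                paste(c(t$tokens, "http://spam.example", "@someone", "the"),
                      collapse = " ")
              }, character(1)),
              rep(1L, 25))
  out <- preprocess_corpus(x, cfg)
  all_tokens <- unlist(lapply(out, `[[`, "tokens"))
  expect_false(any(grepl("^https?://|^www\\.", all_tokens)))
  expect_false(any(startsWith(all_tokens, "@")))
  expect_false(any(all_tokens %in% cfg$stopwords))
  expect_false(any(grepl("(.)\\1{3,}", all_tokens, perl = TRUE)))
  expect_identical(all_tokens, tolower(all_tokens))
})

test_that("tokenized corpora round-trip through JSON-lines", {
  toks <- make_tokens(list(c("hay", "fever"), c("pollen")), labels = c(2L, NA))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tokens(toks, path)
  back <- read_tokens(path)
  expect_identical(lapply(back, unclass), lapply(toks, unclass))
})
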