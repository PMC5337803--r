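test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_tweets = 15, seed = 99, noise = 0.2,
                          decoys = 0.2, inject = 0.5)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$tweets, b$tweets)
  expect_identical(a$gold, b$gold)
  expect_identical(a$lexicon_lines, b$lexicon_lines)
  da <- withr::local_tempdir()
  db <- withr::local_tempdir()
  write_corpus(a, da)
  write_corpus(b, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f), warn = FALSE),
                     readLines(file.path(db, f), warn = FALSE))
  }
})

test_that("manifest counts match the corpus and every gold span is a planted term", {
  corp <- generate_corpus(generator_config(n_tweets = 30, seed = 3))
  expect_identical(corp$manifest$n_tweets, 30L)
  expect_gte(corp$manifest$n_gold, 30L)
  expect_identical(nrow(corp$tweets), 30L)
  gaz_terms <- corp$gazetteer$term
  expect_true(all(corp$gold$term %in% gaz_terms))
  for (i in seq_len(nrow(corp$gold))) {
    tw <- corp$analyzed[[corp$gold$tweet_id[[i]]]]
    span <- (corp$gold$start[[i]] + 1L):corp$gold$end[[i]]
    expect_identical(paste(tw$tokens$lemma[span], collapse = " "),
                     corp$gold$term[[i]])
  }
})

test_that("generated files re-parse through the package readers", {
  corp <- generate_corpus(generator_config(n_tweets = 12, seed = 8,
                                           inject = 0.5))
  d <- withr::local_tempdir()
  write_corpus(corp, d)
  expect_identical(read_tweets(file.path(d, "tweets.jsonl")), corp$tweets)
  gold <- read_gold(file.path(d, "gold.jsonl"))
  expect_identical(gold, corp$gold[, c("tweet_id", "start", "end", "label")])
  lex <- load_lexicon(file.path(d, "lexicon.txt"))
  expect_identical(lex$n_entries, corp$manifest$n_lexicon_entries)
  gaz <- read_gazetteer_tsv(file.path(d, "gazetteer.tsv"))
  expect_identical(gaz, corp$gazetteer)
  ab <- read_abbreviations(file.path(d, "abbrev.tsv"), source = "domain")
  expect_identical(unname(ab$map), unname(corp$abbrev$map))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(label_mix = c(positive = 0.5, negative = 0.5,
                                              neutral = 0.5)), "sum to 1")
  expect_error(generator_config(context_width = c(0L, 0L)), "margin")
  expect_error(generator_config(noise = 1.5))
  expect_error(generator_config(n_tweets = 0))
})

test_that("a noiseless corpus is perfectly recovered by the pipeline", {
  corp <- generate_corpus(generator_config(n_tweets = 60, seed = 21,
                                           noise = 0, decoys = 0))
  lex <- corpus_lexicon(corp)
  gaz <- build_gazetteer(corp$gazetteer)
  pred_spans <- do.call(rbind, lapply(corp$analyzed, detect_aspects,
                                      gazetteer = gaz))
  id <- eval_identification(pred_spans, corp$gold)
  expect_equal(c(id$precision, id$recall, id$f_measure), c(100, 100, 100))
  expect_equal(pipeline_macro_f(corp), 100)
})

test_that("label recovery degrades monotonically with lexicon-dropout noise", {
  mean_f <- function(noise) {
    mean(vapply(1:20, function(s) {
      corp <- generate_corpus(generator_config(n_tweets = 25, seed = 1000 + s,
                                               noise = noise))
      pipeline_macro_f(corp)
    }, numeric(1)))
  }
  f0 <- mean_f(0)
  f3 <- mean_f(0.3)
  f6 <- mean_f(0.6)
  expect_equal(f0, 100)
  expect_lt(f3, f0)
  expect_lte(f6, f3)
})

test_that("the hand fixture carries the worked example and its lexicon entry", {
  fx <- fixture_minimal()
  expect_identical(nrow(fx$tweets), 10L)
  expect_true(any(grepl("glucose tablets", fx$tweets$text)))
  lex <- fixture_lexicon()
  e <- select_sense("better", "JJR", lex)
  expect_equal(c(e$pos, e$neg, e$neu), c(0.875, 0, 0.125))
  # a multiword gazetteer term yields a multiword span
  gaz <- fixture_gazetteer()
  m <- detect_aspects(fx$analyzed[["f01"]], gaz)
  expect_true(any(m$end - m$start == 2L))
  # gold spans re-locate in their analyzed tweets
  for (i in seq_len(nrow(fx$gold))) {
    tw <- fx$analyzed[[fx$gold$tweet_id[[i]]]]
    expect_lte(fx$gold$end[[i]], nrow(tw$tokens))
  }
})
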