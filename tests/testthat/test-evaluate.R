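test_that("precision/recall/F arithmetic matches hand-computed values", {
  r <- prf_counts(3, 1, 2)
  expect_equal(r$precision, 75)
  expect_equal(r$recall, 60)
  expect_equal(round(r$f_measure, 2), 66.67)
  # harmonic mean of rounded P/R lands within a hundredth of the value
  # obtained from the unrounded counts
  expect_lte(abs(round(f_measure(85.71, 80.00), 2) - 82.75), 0.01 + 1e-9)
  expect_equal(f_measure(0, 0), 0)
  # min(P,R) <= F <= max(P,R), with equality when P = R
  for (tp in c(0, 3, 10)) for (fp in 0:3) for (fn in 0:3) {
    if (tp + fp == 0 || tp + fn == 0) next
    r <- prf_counts(tp, fp, fn)
    expect_gte(r$f_measure, min(r$precision, r$recall) - 1e-9)
    expect_lte(r$f_measure, max(r$precision, r$recall) + 1e-9)
    if (fp == fn) expect_equal(r$f_measure, r$precision)
  }
})

gold4 <- data.frame(tweet_id = c("a", "a", "b", "c"),
                    start = c(0L, 4L, 1L, 2L), end = c(2L, 5L, 2L, 3L),
                    label = c("positive", "positive", "negative", "neutral"),
                    stringsAsFactors = FALSE)

test_that("identification matching in exact and overlap modes", {
  pred <- gold4[, c("tweet_id", "start", "end")]
  r <- eval_identification(pred, gold4)
  expect_equal(c(r$precision, r$recall, r$f_measure), c(100, 100, 100))
  # swapping pred and gold swaps P and R in exact mode
  pred2 <- data.frame(tweet_id = c("a", "a", "d"), start = c(0L, 4L, 0L),
                      end = c(2L, 5L, 1L), stringsAsFactors = FALSE)
  fwd <- eval_identification(pred2, gold4)
  rev <- eval_identification(gold4[, 1:3], pred2)
  expect_equal(fwd$precision, rev$recall)
  expect_equal(fwd$recall, rev$precision)
  # overlap mode: off-by-one span still counts
  pred3 <- data.frame(tweet_id = "a", start = 1L, end = 3L,
                      stringsAsFactors = FALSE)
  expect_identical(eval_identification(pred3, gold4, mode = "exact")$tp, 0L)
  expect_identical(eval_identification(pred3, gold4, mode = "overlap")$tp, 1L)
  expect_error(eval_identification(pred, rbind(gold4, gold4[1, ])),
               "duplicate gold")
})

test_that("polarity metrics agree with a confusion-matrix oracle", {
  pred <- gold4
  pred$label <- c("positive", "negative", "negative", "neutral")
  ev <- eval_polarity(pred, gold4)
  want <- oracle_polarity_prf(pred$label, gold4$label)
  expect_equal(ev$macro$precision, want$macro_p)
  expect_equal(ev$macro$recall, want$macro_r)
  expect_equal(ev$macro$f_measure, want$macro_f)
  # hand arithmetic: pos P=1/1, R=1/2; neg P=1/2, R=1/1; neu P=R=1
  expect_equal(ev$macro$precision, mean(c(100, 50, 100)))
  expect_equal(ev$macro$recall, mean(c(50, 100, 100)))
  # micro recall equals accuracy on matched aspects
  expect_equal(ev$micro$recall, 100 * 3 / 4)
  expect_equal(ev$micro$precision, ev$micro$recall)
  expect_identical(ev$n_matched, 4L)
})

test_that("all-correct predictions give macro 100 and zero matches give zeros", {
  ev <- eval_polarity(gold4, gold4)
  expect_equal(c(ev$macro$precision, ev$macro$recall, ev$macro$f_measure),
               c(100, 100, 100))
  none <- data.frame(tweet_id = "z", start = 0L, end = 1L,
                     label = "positive", stringsAsFactors = FALSE)
  expect_warning(ev0 <- eval_polarity(none, gold4), "no identification")
  expect_equal(ev0$overall$f_measure, 0)
  bad <- gold4
  bad$label[1] <- "meh"
  expect_error(eval_polarity(gold4, bad), "invalid polarity label")
})

test_that("run_sweep covers the requested grid deterministically", {
  corp <- generate_corpus(generator_config(n_tweets = 40, seed = 5))
  lex <- corpus_lexicon(corp)
  gaz <- build_gazetteer(corp$gazetteer)
  one <- run_sweep(corp$analyzed, corp$gold, lex, gaz,
                   methods = "before", n_values = 3)
  expect_identical(nrow(one$cells), 1L)
  full <- run_sweep(corp$analyzed, corp$gold, lex, gaz)
  expect_identical(nrow(full$cells), 15L)
  expect_setequal(unique(full$cells$method), c("before", "after", "around"))
  expect_identical(sort(unique(full$cells$n)), 2:6)
  again <- run_sweep(corp$analyzed, corp$gold, lex, gaz)
  expect_identical(full$cells, again$cells)
  # serialization round-trips the cell grid
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(full, tsv)
  back <- utils::read.delim(tsv)
  expect_identical(nrow(back), 15L)
  expect_identical(names(back)[1:2], c("method", "n"))
})
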