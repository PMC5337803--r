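test_that("the lexicon parser enforces the SentiWordNet format contract", {
  lex <- fixture_lexicon()
  e <- lex$entries[["a|00230335"]]
  expect_equal(c(e$pos, e$neg, e$neu), c(0.875, 0, 0.125))
  # comment lines do not count as entries
  n0 <- lex$n_entries
  lex2 <- lexicon_from_lines(c("# a comment",
                               "a\t00000001\t0.5\t0.25\tgood#1\tgloss"))
  expect_identical(lex2$n_entries, 1L)
  expect_equal(lex2$entries[["a|00000001"]]$neu, 0.25)
  expect_error(lexicon_from_lines("a\t00000001\t0.7\t0.6\tx#1\tg"),
               "exceeds 1")
  expect_error(lexicon_from_lines("a\t123\t0.1\t0.1\tx#1\tg"), "8 digits")
  expect_error(lexicon_from_lines("z\t00000001\t0.1\t0.1\tx#1\tg"), "a/n/r/v")
  expect_error(lexicon_from_lines("a\t00000001\t0.1"), "line 1")
  expect_gt(n0, 5L)
})

test_that("every parsed sense triple sums to one", {
  lex <- fixture_lexicon()
  for (key in ls(lex$entries)) {
    e <- lex$entries[[key]]
    expect_equal(e$pos + e$neg + e$neu, 1, tolerance = 1e-9)
    expect_true(all(c(e$pos, e$neg, e$neu) >= 0))
  }
})

test_that("sense selection maps Penn tags and falls back to the smallest rank", {
  lex <- fixture_lexicon()
  e <- select_sense("better", "JJR", lex)
  expect_identical(e$synset_id, "00230335")  # rank-1 adjective sense
  expect_equal(e$pos, 0.875)
  expect_null(select_sense("the", "DT", lex))     # unmappable category
  expect_null(select_sense("zzz", "NN", lex))     # absent lemma
  # explicit two-sense fixture: rank 1 wins regardless of file order
  lex2 <- lexicon_from_lines(c("a\t00000002\t0\t0.5\tamb#2\tsecond sense",
                               "a\t00000001\t0.5\t0\tamb#1\tfirst sense"))
  expect_identical(select_sense("amb", "JJ", lex2)$synset_id, "00000001")
})

test_that("the polarity rule is strict, total, and ties go neutral", {
  expect_identical(classify_polarity(c(0.875, 0, 0.125)), "positive")
  expect_identical(classify_polarity(c(0, 0, 0)), "neutral")
  expect_identical(classify_polarity(c(0.2, 0.5, 0.3)), "negative")
  expect_identical(classify_polarity(c(0.5, 0.5, 0.1)), "neutral")  # tie
  expect_error(classify_polarity(c(-0.1, 0, 0)), "nonnegative")
  # totality and single-valuedness on a dense grid
  grid <- seq(0, 1, by = 0.1)
  for (p in grid) for (ng in grid) for (nu in grid) {
    lab <- classify_polarity(c(p, ng, nu))
    if (p > max(ng, nu)) {
      expect_identical(lab, "positive")
    } else if (ng > max(p, nu)) {
      expect_identical(lab, "negative")
    } else {
      # nu strictly largest, or a tie for the maximum: both are neutral
      expect_identical(lab, "neutral")
    }
  }
})

test_that("aspect scores are additive sums of per-word triples", {
  fx <- fixture_minimal()
  lex <- fixture_lexicon()
  tw <- fx$analyzed[["f01"]]
  gaz <- fixture_gazetteer()
  asps <- detect_aspects(tw, gaz)
  gl <- asps[asps$concept_id == "DDO:0003", ]  # glucose tablets
  w <- extract_window(tw, gl, method = "after", n = 4)
  s <- score_aspect(w, tw, lex)
  # only "better" (0.875, 0, 0.125) contributes among might/be/a/better
  expect_equal(c(s$pos, s$neg, s$neu), c(0.875, 0, 0.125))
  expect_identical(s$label, "positive")
  expect_equal(s$pos, sum(s$per_word$pos))
  expect_equal(s$neu, sum(s$per_word$neu))
  # empty window: zero triple, neutral by the tie rule
  w0 <- extract_window(tw, list(start = 0L, end = 1L), method = "before", n = 3)
  s0 <- score_aspect(w0, tw, lex)
  expect_equal(c(s0$pos, s0$neg, s0$neu), c(0, 0, 0))
  expect_identical(s0$label, "neutral")
})

test_that("scores match a brute-force accumulator and are permutation invariant", {
  corp <- generate_corpus(generator_config(n_tweets = 30, seed = 17))
  lex <- corpus_lexicon(corp)
  gaz <- build_gazetteer(corp$gazetteer)
  for (tw in corp$analyzed[1:30]) {
    asps <- detect_aspects(tw, gaz)
    for (i in seq_len(nrow(asps))) {
      w <- extract_window(tw, asps[i, ], method = "around", n = 3)
      s <- score_aspect(w, tw, lex)
      want <- oracle_score_triple(tw, w$token_indices, lex)
      expect_equal(c(s$pos, s$neg, s$neu), want)
      # permuting the window leaves the aggregate unchanged
      wp <- w
      wp$token_indices <- rev(w$token_indices)
      sp <- score_aspect(wp, tw, lex)
      expect_equal(c(sp$pos, sp$neg, sp$neu), c(s$pos, s$neg, s$neu))
    }
  }
})

test_that("adding a purely positive word never flips positive to negative", {
  lex <- lexicon_from_lines(c(
    "n\t00000001\t0.75\t0\tposword#1\tg",
    "n\t00000002\t0\t0.875\tnegword#1\tg",
    "n\t00000003\t0.625\t0\tboost#1\tg",
    "n\t00000004\t0\t0\ttarget#1\tg"))
  gaz <- build_gazetteer(data.frame(concept_id = "X", term = "target"))
  base <- "posword target posword"
  for (extra in 1:4) {
    text <- paste(c(base, rep("boost", extra)), collapse = " ")
    tw <- preprocess_tweet("t", text)
    asp <- detect_aspects(tw, gaz)
    s <- score_aspect(extract_window(tw, asp, "around", 6), tw, lex)
    expect_identical(s$label, "positive")
  }
})

test_that("pipeline labels equal a flat-loop reimplementation on the fixture corpus", {
  corp <- generate_corpus(generator_config(n_tweets = 20, seed = 23,
                                           inject = 0.5))
  lex <- corpus_lexicon(corp)
  gaz <- build_gazetteer(corp$gazetteer)
  pred <- annotate_corpus(corp$analyzed, gaz, lex, method = "around", n = 3)
  for (r in seq_len(nrow(pred))) {
    tw <- corp$analyzed[[pred$tweet_id[[r]]]]
    idx <- oracle_window(tw, list(start = pred$start[[r]], end = pred$end[[r]]),
                         "around", 3)
    tri <- oracle_score_triple(tw, idx, lex)
    lab <- if (tri[1] > tri[2] && tri[1] > tri[3]) "positive"
           else if (tri[2] > tri[1] && tri[2] > tri[3]) "negative"
           else "neutral"
    expect_identical(pred$label[[r]], lab)
  }
})
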