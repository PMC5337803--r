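test_that("normalization strips mentions, URLs and hashtag marks and expands abbreviations", {
  d <- abbrev_dict(c(carbs = "carbohydrates"), source = "domain")
  out <- normalize_tweet("@user1 my carbs spiked http://t.co/xyz #diabetes",
                         dicts = list(d))
  expect_identical(out$text, "my carbohydrates spiked diabetes")
  expect_identical(normalize_tweet("")$text, "")
  d2 <- abbrev_dict(c(hypo = "Hypoglycemia"), source = "domain")
  expect_identical(normalize_tweet("Hypo alert", dicts = list(d2))$text,
                   "Hypoglycemia alert")
  # https and bare shortener forms are URLs too
  expect_identical(normalize_tweet("see https://x.y/z and t.co/q now")$text,
                   "see and now")
})

test_that("domain dictionary wins over SMS and longest key wins", {
  sms <- abbrev_dict(c(bg = "big grin"), source = "sms")
  dom <- abbrev_dict(c(bg = "blood glucose", "bg level" = "blood glucose level"),
                     source = "domain")
  expect_identical(normalize_tweet("bg high", dicts = list(sms, dom))$text,
                   "blood glucose high")
  expect_identical(normalize_tweet("bg level high", dicts = list(sms, dom))$text,
                   "blood glucose level high")
})

test_that("removal rules are idempotent and the edit log replays exactly", {
  d <- abbrev_dict(c(carbs = "carbohydrates", hypo = "Hypoglycemia"),
                   source = "domain")
  raws <- c("@a @b ## ###x  http://q.r   trailing ",
            "plain text with no specials",
            "#Hypo  and   carbs @someone",
            "", "@only", "#", "http://alone.example",
            "tabs\tand\nnewlines  here")
  for (raw in raws) {
    one <- normalize_tweet(raw, dicts = list(d))
    two <- normalize_tweet(one$text, dicts = list())
    expect_identical(two$text, one$text)  # removals already exhausted
    expect_false(grepl("[#@]|http", two$text))
    expect_identical(apply_edit_log(raw, one$edit_log), one$text)
  }
})

test_that("spell corrector is deterministic and runs after abbreviation expansion", {
  corr <- corrector_dictionary(c("glucose", "glucagon"), max_distance = 1)
  out <- normalize_tweet("glucos level", dicts = list(), corrector = corr)
  expect_identical(out$text, "glucose level")
  # a tie at equal distance resolves to the lexicographically first word
  corr2 <- corrector_dictionary(c("cat", "bat"), max_distance = 1)
  expect_identical(corr2$correct("aat"), "bat")
  # the abbreviation key expands before the corrector can touch it
  d <- abbrev_dict(c(hypo = "Hypoglycemia"), source = "domain")
  corr3 <- corrector_dictionary(c("hype", "typo"), max_distance = 1)
  out3 <- normalize_tweet("Hypo", dicts = list(d), corrector = corr3)
  expect_identical(out3$text, "Hypoglycemia")
})

test_that("analysis reproduces the worked token/POS/lemma block", {
  tw <- preprocess_tweet("t1", paste(
    "When people with diabetes experience a dangerous drop in blood sugar ,",
    "glucose tablets might be a better option than a sugary food or drink"))
  tok <- tw$tokens
  expect_identical(tok$pos[tok$surface == "When"], "WRB")
  expect_identical(tok$lemma[tok$surface == "When"], "when")
  expect_identical(tok$pos[tok$surface == "people"], "NNS")
  expect_identical(tok$pos[tok$surface == "tablets"], "NNS")
  expect_identical(tok$lemma[tok$surface == "tablets"], "tablet")
  expect_identical(tok$pos[tok$surface == "better"], "JJR")
  expect_identical(tok$pos[tok$surface == "dangerous"], "JJ")
  expect_identical(tok$pos[tok$surface == "might"], "MD")
  expect_identical(tok$pos[tok$surface == ","], ",")
  expect_false(any(tok$is_word[tok$surface == ","]))
  # inflected verbs map to their base form
  expect_identical(penn_backend()$tag("buys")$lemma, "buy")
  expect_identical(penn_backend()$tag("buying")$lemma, "buy")
})

test_that("sentences partition tokens and end at ., ! or ?", {
  tw <- preprocess_tweet("t1", "sugar high ! insulin low . all fine now")
  s <- tw$sentences
  expect_identical(s$start, c(0L, 3L, 6L))
  expect_identical(s$end, c(3L, 6L, 9L))
  expect_identical(s$start[-1L], s$end[-nrow(s)])  # contiguous partition
  # runs of enders close a single sentence
  tw2 <- preprocess_tweet("t2", "what ?! really")
  expect_identical(nrow(tw2$sentences), 2L)
  expect_identical(nrow(preprocess_tweet("t3", "")$sentences), 0L)
})

test_that("token surfaces reconstruct the normalized word content", {
  corp <- generate_corpus(generator_config(n_tweets = 25, seed = 7))
  for (tw in corp$analyzed) {
    rebuilt <- paste(tw$tokens$surface, collapse = " ")
    stripped <- gsub("\\s+", " ", gsub("([^A-Za-z0-9' ])", " \\1 ",
                                       tw$normalized_text))
    expect_identical(trimws(gsub("\\s+", " ", rebuilt)), trimws(stripped))
  }
})

test_that("analysis is deterministic and the backend is validated", {
  a <- preprocess_tweet("x", "glucose tablets might be a better option")
  b <- preprocess_tweet("x", "glucose tablets might be a better option")
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_error(analyze_text("text", backend = NULL), "backend")
  expect_error(analyze_text("text", backend = list(name = "broken")), "backend")
})
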