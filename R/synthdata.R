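# Synthetic corpus generator. Produces miniature tweets with planted
# gazetteer aspects whose surrounding context words carry known lexicon
# triples, so the gold polarity label is guaranteed by construction: the
# planted words of a tweet all pull toward the gold label and the margin
# between the top two aggregate components is at least 0.1, which is what
# the strict-inequality decision rule needs. The generator emulates the
# pipeline's contracts (polar words concentrated near aspects, mentions/
# URLs/hashtags/abbreviations to exercise preprocessing), not real Twitter
# language statistics.

# pronounceable nonsense-word syllables; final syllables avoid every suffix
# the tagger treats specially (-s, -y, -ly, -ing, -ed, -ous, -al, ...), so
# every generated word is tagged NN with lemma == lowercase surface.
.syl_start <- c("ba", "ke", "di", "fo", "gu", "ha", "ji", "lo", "mu", "na",
                "pe", "ri", "so", "tu", "va", "we", "zi", "bo", "ce", "du")
.syl_end <- c("fan", "tor", "mek", "lun", "dop", "rik", "gon", "bex", "tul",
              "vom", "nid", "pru", "zor", "kem", "lat", "bin", "dur", "mot")

make_words <- function(k, avoid = character()) {
  pool <- as.vector(outer(.syl_start, .syl_end, paste0))
  pool <- c(pool, as.vector(outer(pool, .syl_end, paste0)))
  pool <- setdiff(pool, c(avoid, names(.penn_closed), names(.penn_lexical)))
  if (k > length(pool)) stop("vocabulary pool exhausted (asked for ", k, ")")
  sample(pool, k)
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the corpus the pipeline is designed for: 900 tweets,
#' one annotated aspect each, the three polarity labels balanced, and one
#' to three polar context words on each side of the aspect (the pipeline's
#' best-performing window covers three words per side).
#'
#' @param n_tweets number of tweets (>= 1).
#' @param n_concepts number of gazetteer concepts.
#' @param multiword_share share of concepts whose term is two words.
#' @param polar_vocab_size polar words per polarity class.
#' @param context_width integer range `c(min, max)` of planted polar words
#'   on each side of the aspect; values 0..6 allowed, but `max >= 1` is
#'   required so every label's margin is attainable.
#' @param label_mix named proportions of positive/negative/neutral aspects
#'   (must sum to 1).
#' @param noise probability a planted context word is replaced by a word
#'   absent from the lexicon (gold label unchanged, so labels degrade).
#' @param decoys probability a tweet carries a near-miss phrase built from
#'   a multiword term with its tail word altered, absent from the gazetteer.
#' @param inject probability a tweet gets a mention, URL, hashtag or
#'   abbreviation to exercise preprocessing.
#' @param multisense_rate share of polar words given a second, higher-rank
#'   sense, exercising the sense selector.
#' @param seed RNG seed recorded in the manifest.
#' @return a validated `generator_config`.
#' @export
generator_config <- function(n_tweets = 900L, n_concepts = 12L,
                             multiword_share = 1 / 3, polar_vocab_size = 30L,
                             context_width = c(1L, 3L),
                             label_mix = c(positive = 1 / 3, negative = 1 / 3,
                                           neutral = 1 / 3),
                             noise = 0, decoys = 0, inject = 0.25,
                             multisense_rate = 0.2, seed = 1L) {
  stopifnot(n_tweets >= 1L, n_concepts >= 1L, polar_vocab_size >= 3L,
            length(context_width) == 2L, context_width[[1L]] >= 0L,
            context_width[[2L]] >= context_width[[1L]],
            context_width[[2L]] <= 6L,
            noise >= 0, noise <= 1, decoys >= 0, decoys <= 1,
            inject >= 0, inject <= 1,
            multisense_rate >= 0, multisense_rate <= 1,
            multiword_share >= 0, multiword_share <= 1)
  if (abs(sum(label_mix) - 1) > 1e-9) stop("label_mix must sum to 1")
  if (!all(c("positive", "negative", "neutral") %in% names(label_mix))) {
    stop("label_mix needs positive/negative/neutral proportions")
  }
  if (context_width[[2L]] < 1L) {
    stop("context_width max of 0 makes every label's margin impossible")
  }
  structure(list(n_tweets = as.integer(n_tweets),
                 n_concepts = as.integer(n_concepts),
                 multiword_share = multiword_share,
                 polar_vocab_size = as.integer(polar_vocab_size),
                 context_width = as.integer(context_width),
                 label_mix = label_mix[c("positive", "negative", "neutral")],
                 noise = noise, decoys = decoys, inject = inject,
                 multisense_rate = multisense_rate, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic annotated corpus
#'
#' Builds, deterministically under the configured seed: a fixture lexicon
#' (SentiWordNet text format), a gazetteer term list, abbreviation
#' dictionaries, raw tweets, and gold aspect/polarity annotations whose
#' token spans refer to the preprocessed tweets. Each tweet contains exactly
#' one planted aspect surrounded by polar words of the gold label's class;
#' the summed planted triples leave a margin of at least 0.1 between the top
#' two aggregate components, so a window covering the planted context
#' recovers the gold label exactly.
#'
#' @param config a [generator_config()].
#' @return a `synthetic_corpus`: `tweets` (data.frame id/text), `gold`,
#'   `lexicon_lines`, `gazetteer` (data.frame), `abbrev` ([abbrev_dict()]),
#'   `analyzed` (preprocessed `tweet` objects) and `manifest`.
#' @examples
#' corp <- generate_corpus(generator_config(n_tweets = 5, seed = 42))
#' corp$tweets$text[1:2]
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n_multi <- round(config$n_concepts * config$multiword_share)
  n_single <- config$n_concepts - n_multi
  v <- config$polar_vocab_size
  words <- make_words(n_single + 2L * n_multi + 3L * v + 12L)
  concept_single <- words[seq_len(n_single)]
  off <- n_single
  concept_multi <- if (n_multi > 0L) {
    matrix(words[off + seq_len(2L * n_multi)], ncol = 2L)
  } else {
    matrix(character(), ncol = 2L)
  }
  off <- off + 2L * n_multi
  vocab <- list(positive = words[off + seq_len(v)],
                negative = words[off + v + seq_len(v)],
                neutral = words[off + 2L * v + seq_len(v)])
  off <- off + 3L * v
  abbrev_keys <- words[off + seq_len(6L)]
  abbrev_expansions <- words[off + 6L + seq_len(6L)]
  # filler words are drawn fresh and never entered into the lexicon
  filler_pool <- make_words(60L, avoid = words)

  # --- fixture lexicon (SWN 3.0 text format) ------------------------------
  lex_lines <- c("# synthetic SentiWordNet-format fixture lexicon",
                 "# POS\tID\tPosScore\tNegScore\tSynsetTerms\tGloss")
  sid <- 0L
  next_id <- function() {
    sid <<- sid + 1L
    sprintf("%08d", sid)
  }
  strengths <- c(0.625, 0.75, 0.875)
  triples <- list()
  for (cls in c("positive", "negative", "neutral")) {
    for (w in vocab[[cls]]) {
      s <- sample(strengths, 1L)
      tri <- switch(cls,
                    positive = c(s, 0, 1 - s),
                    negative = c(0, s, 1 - s),
                    neutral = c(0, 0, 1))
      triples[[w]] <- tri
      lex_lines <- c(lex_lines, sprintf(
        "n\t%s\t%s\t%s\t%s#1\tsynthetic %s sense of %s",
        next_id(), format(tri[[1L]], trim = TRUE),
        format(tri[[2L]], trim = TRUE), w, cls, w))
      if (runif(1) < config$multisense_rate) {
        # a second, higher-rank sense the fallback selector must skip
        lex_lines <- c(lex_lines, sprintf(
          "n\t%s\t0\t0\t%s#2\tsynthetic distractor sense of %s",
          next_id(), w, w))
      }
    }
  }

  # --- gazetteer ----------------------------------------------------------
  multi_terms <- if (nrow(concept_multi)) {
    paste(concept_multi[, 1L], concept_multi[, 2L])
  } else {
    character()
  }
  gaz <- data.frame(
    concept_id = sprintf("SYN:%04d", seq_len(config$n_concepts)),
    term = c(concept_single, multi_terms),
    stringsAsFactors = FALSE)

  # --- abbreviation dictionaries ------------------------------------------
  abbrev <- abbrev_dict(setNames(abbrev_expansions, abbrev_keys),
                        source = "domain")

  # --- tweets -------------------------------------------------------------
  labels <- sample(names(config$label_mix), config$n_tweets, replace = TRUE,
                   prob = as.numeric(config$label_mix))
  ids <- sprintf("t%04d", seq_len(config$n_tweets))
  texts <- character(config$n_tweets)
  gold_rows <- vector("list", config$n_tweets)
  wmin <- config$context_width[[1L]]
  wmax <- config$context_width[[2L]]
  for (t in seq_len(config$n_tweets)) {
    label <- labels[[t]]
    ci <- sample.int(config$n_concepts, 1L)
    term <- gaz$term[[ci]]
    wl <- sample_range(wmin, wmax)
    wr <- sample_range(wmin, wmax)
    if (wl + wr == 0L) wr <- 1L  # at least one polar word for the margin
    left <- sample(vocab[[label]], wl, replace = TRUE)
    right <- sample(vocab[[label]], wr, replace = TRUE)
    noisy <- runif(wl + wr) < config$noise
    ctx <- c(left, right)
    ctx[noisy] <- sample(filler_pool, sum(noisy), replace = TRUE)
    left <- ctx[seq_len(wl)]
    right <- ctx[wl + seq_len(wr)]
    lead <- sample(filler_pool, sample(0:2, 1L), replace = TRUE)
    trail <- sample(filler_pool, sample(0:2, 1L), replace = TRUE)
    parts <- c(lead, left, term, right, trail)
    if (runif(1) < config$decoys && nrow(concept_multi) > 0L) {
      dm <- concept_multi[sample.int(nrow(concept_multi), 1L), ]
      parts <- c(parts, paste(dm[[1L]], sample(filler_pool, 1L)))
    }
    if (runif(1) < config$inject) {
      kind <- sample(c("mention", "url", "hashtag", "abbrev"), 1L)
      parts <- switch(kind,
                      mention = c(sprintf("@user%d", t), parts),
                      url = c(parts, sprintf("http://t.co/%04d", t)),
                      hashtag = c(parts, paste0("#", sample(filler_pool, 1L))),
                      abbrev = c(sample(abbrev_keys, 1L), parts))
    }
    text <- paste(parts, collapse = " ")
    if (runif(1) < 0.5) text <- paste0(text, " .")
    texts[[t]] <- text
    gold_rows[[t]] <- list(concept_id = gaz$concept_id[[ci]], term = term,
                           label = label)
  }
  tweets <- data.frame(id = ids, text = texts, stringsAsFactors = FALSE)

  # --- gold spans: locate each planted term in the analyzed tweet ---------
  analyzed <- preprocess_corpus(tweets, dicts = list(abbrev))
  gold <- do.call(rbind, lapply(seq_len(config$n_tweets), function(t) {
    tw <- analyzed[[t]]
    term_words <- strsplit(gold_rows[[t]]$term, " ", fixed = TRUE)[[1L]]
    span <- find_subsequence(tw$tokens$lemma, term_words)
    if (is.null(span)) stop("planted term not recoverable in tweet ", ids[[t]])
    data.frame(tweet_id = ids[[t]], start = span[[1L]], end = span[[2L]],
               label = gold_rows[[t]]$label,
               concept_id = gold_rows[[t]]$concept_id,
               term = gold_rows[[t]]$term, stringsAsFactors = FALSE)
  }))

  manifest <- list(generator = "aspectsent synthetic corpus",
                   seed = config$seed,
                   config = unclass(config),
                   n_tweets = nrow(tweets), n_gold = nrow(gold),
                   n_lexicon_entries = sid,
                   n_concepts = config$n_concepts)
  structure(list(tweets = tweets, gold = gold, lexicon_lines = lex_lines,
                 gazetteer = gaz, abbrev = abbrev, analyzed = analyzed,
                 manifest = manifest),
            class = "synthetic_corpus")
}

# sample() treats a scalar first argument as 1:x; avoid that trap
sample_range <- function(lo, hi) {
  if (lo == hi) lo else sample(lo:hi, 1L)
}

# first occurrence of `needle` as a contiguous subsequence; 0-based half-open
find_subsequence <- function(haystack, needle) {
  k <- length(needle)
  if (k == 0L || length(haystack) < k) return(NULL)
  for (i in seq_len(length(haystack) - k + 1L)) {
    if (all(haystack[i:(i + k - 1L)] == needle)) {
      return(c(i - 1L, i - 1L + k))
    }
  }
  NULL
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$tweets), " tweets, ", nrow(x$gold),
      " gold aspects, ", x$manifest$n_lexicon_entries, " lexicon entries, ",
      nrow(x$gazetteer), " gazetteer terms (seed ", x$manifest$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic corpus to a directory
#'
#' Writes `tweets.jsonl`, `gold.jsonl`, `lexicon.txt` (SentiWordNet text
#' format), `gazetteer.tsv`, `abbrev.tsv` and `manifest.json`. Regenerating
#' with the manifest's config and seed reproduces the files byte for byte.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if missing).
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tweets_jsonl(corpus$tweets, file.path(dir, "tweets.jsonl"))
  write_gold_jsonl(corpus$gold, file.path(dir, "gold.jsonl"))
  writeLines(corpus$lexicon_lines, file.path(dir, "lexicon.txt"),
             useBytes = TRUE)
  write_gazetteer_tsv(corpus$gazetteer, file.path(dir, "gazetteer.tsv"))
  writeLines(paste(names(corpus$abbrev$map), corpus$abbrev$map, sep = "\t"),
             file.path(dir, "abbrev.tsv"), useBytes = TRUE)
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load the lexicon bundled inside a synthetic corpus
#'
#' Round-trips the in-memory lexicon lines through a temporary file and
#' [load_lexicon()], so the corpus lexicon always passes the same parser as
#' an external file would.
#'
#' @param corpus a `synthetic_corpus`.
#' @export
corpus_lexicon <- function(corpus) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(corpus$lexicon_lines, f, useBytes = TRUE)
  load_lexicon(f)
}

#' Hand-written minimal fixture corpus
#'
#' Ten small tweets covering the pipeline's tricky paths: a multiword-aspect
#' tweet about a dangerous blood-sugar drop where glucose tablets are the
#' better option, mention/URL/hashtag tweets, abbreviation tweets ("Hypo",
#' "carbs"), a near-miss phrase absent from the gazetteer, and an empty-ish
#' tweet. The bundled fixture lexicon contains the adjective sense of
#' "better" with scores (0.875, 0, 0.125) plus entries for the polar context
#' words; the fixture gazetteer holds diabetes-domain concepts including
#' two-word terms. Gold labels are hand-assigned; gold spans are located in
#' the analyzed tokens at build time.
#'
#' @return a `synthetic_corpus` (with `manifest$generator = "fixture"`).
#' @export
fixture_minimal <- function() {
  tweets <- data.frame(
    id = sprintf("f%02d", 1:10),
    text = c(
      paste("When people with diabetes experience a dangerous drop in blood",
            "sugar , glucose tablets might be a better option than a sugary",
            "food or drink ."),
      "@doc42 insulin pump working great today http://t.co/ab12 #diabetes",
      "Hypo alert after skipping lunch , feeling terrible",
      "my carbs spiked badly after that sugary drink",
      "metformin is a safe option for most people",
      "oral antihyperglycemic agents are rarely mentioned here",
      "oral hypoglycemic therapy seems a better option",
      "blood sugar stable , HbA1c test results fine",
      "nothing about the domain in this tweet at all",
      "insulin ."),
    stringsAsFactors = FALSE)
  labels <- list(
    f01 = c("neutral", "negative", "positive"),  # diabetes, blood sugar, glucose tablets
    f02 = c("positive", "neutral"),              # insulin pump, diabetes (hashtag)
    f03 = c("negative"),                         # hypoglycemia (from "Hypo")
    f04 = c("negative"),                         # carbohydrates (from "carbs")
    f05 = c("positive"),                         # metformin
    f06 = character(),                           # near-miss: not in gazetteer
    f07 = c("positive"),                         # oral hypoglycemic
    f08 = c("neutral", "neutral"),               # blood sugar, hba1c test
    f09 = character(),
    f10 = c("neutral"))                          # insulin, bare

  sms <- abbrev_dict(c(u = "you", gr8 = "great"), source = "sms")
  domain <- abbrev_dict(c(hypo = "Hypoglycemia", carbs = "carbohydrates"),
                        source = "domain")
  gaz_path <- system.file("extdata", "gazetteer-fixture.tsv",
                          package = "aspectsent")
  lex_path <- system.file("extdata", "swn-fixture.txt",
                          package = "aspectsent")
  gaz_df <- read_gazetteer_tsv(gaz_path)
  gazetteer <- build_gazetteer(gaz_df)
  analyzed <- preprocess_corpus(tweets, dicts = list(domain, sms))
  gold <- do.call(rbind, lapply(names(analyzed), function(id) {
    mention <- detect_aspects(analyzed[[id]], gazetteer)
    lab <- labels[[id]]
    if (nrow(mention) != length(lab)) {
      stop("fixture gold mismatch in ", id, ": ", nrow(mention),
           " mentions vs ", length(lab), " labels")
    }
    if (!nrow(mention)) return(NULL)
    data.frame(tweet_id = id, start = mention$start, end = mention$end,
               label = lab, concept_id = mention$concept_id,
               term = mention$surface, stringsAsFactors = FALSE)
  }))
  structure(list(tweets = tweets, gold = gold,
                 lexicon_lines = readLines(lex_path, warn = FALSE),
                 gazetteer = gaz_df, abbrev = domain, analyzed = analyzed,
                 manifest = list(generator = "fixture", seed = NA_integer_,
                                 n_tweets = nrow(tweets),
                                 n_gold = nrow(gold))),
            class = "synthetic_corpus")
}
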