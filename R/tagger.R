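# Deterministic rule/lexicon Penn Treebank tagger + lemmatizer.
#
# Tagging is a pluggable backend behind a fixed contract: a backend is a
# list(name, tag) where tag(surfaces) returns a data.frame(pos, lemma) with
# one row per surface. The default backend below is context-free: a
# closed-class lexicon, a small open-class override lexicon, then suffix
# rules, defaulting to NN. That is deliberately simple but fully
# deterministic and covers the tag inventory this pipeline consumes
# (NN*/VB*/JJ*/RB* drive the lexicon lookup; everything else is ignored by
# scoring).

.penn_closed <- c(
  a = "DT", an = "DT", the = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", no = "DT", some = "DT", any = "DT", every = "DT", each = "DT",
  and = "CC", or = "CC", but = "CC", nor = "CC",
  "in" = "IN", of = "IN", with = "IN", on = "IN", at = "IN", by = "IN",
  "for" = "IN", from = "IN", than = "IN", about = "IN", into = "IN",
  over = "IN", under = "IN", after = "IN", before = "IN", "if" = "IN",
  because = "IN", "while" = "IN", since = "IN", as = "IN", during = "IN",
  to = "TO",
  might = "MD", may = "MD", can = "MD", could = "MD", will = "MD",
  would = "MD", shall = "MD", should = "MD", must = "MD",
  when = "WRB", where = "WRB", why = "WRB", how = "WRB",
  who = "WP", whom = "WP", what = "WP", which = "WDT",
  i = "PRP", you = "PRP", he = "PRP", she = "PRP", it = "PRP", we = "PRP",
  they = "PRP", me = "PRP", him = "PRP", us = "PRP", them = "PRP",
  my = "PRP$", your = "PRP$", his = "PRP$", its = "PRP$", our = "PRP$",
  their = "PRP$",
  not = "RB", very = "RB", too = "RB", so = "RB", also = "RB", now = "RB",
  then = "RB", here = "RB", never = "RB", always = "RB",
  be = "VB", is = "VBZ", am = "VBP", are = "VBP", was = "VBD", were = "VBD",
  been = "VBN", being = "VBG",
  do = "VBP", does = "VBZ", did = "VBD",
  have = "VBP", has = "VBZ", had = "VBD",
  there = "EX")

# open-class overrides (irregular comparatives, plurals, domain words the
# suffix rules would mis-handle)
.penn_lexical <- c(
  better = "JJR", worse = "JJR", best = "JJS", worst = "JJS", more = "JJR",
  less = "JJR", good = "JJ", bad = "JJ", great = "JJ", new = "JJ",
  high = "JJ", low = "JJ", safe = "JJ", free = "JJ", fine = "JJ",
  stable = "JJ",
  people = "NNS", children = "NNS", men = "NNS", women = "NNS", feet = "NNS",
  diabetes = "NN", news = "NN", series = "NN", species = "NN", glucose = "NN",
  insulin = "NN", sugar = "NN", blood = "NN", drop = "NN", drink = "NN",
  experience = "NN", option = "NN", food = "NN")

.lemma_irregular <- c(
  is = "be", am = "be", are = "be", was = "be", were = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have", does = "do",
  did = "do", done = "do", people = "people", children = "child",
  men = "man", women = "woman", feet = "foot", teeth = "tooth",
  mice = "mouse", better = "better", best = "best", worse = "worse",
  worst = "worst", diabetes = "diabetes", news = "news", series = "series",
  species = "species")

# base verbs consulted when undoing -s / -ing / -ed inflection
.verb_stems <- c(
  "buy", "take", "make", "go", "get", "feel", "help", "use", "need", "eat",
  "give", "keep", "run", "try", "want", "work", "know", "think", "say",
  "see", "come", "look", "find", "tell", "ask", "seem", "leave", "call",
  "manage", "check", "test", "inject", "monitor", "control", "improve",
  "reduce", "increase", "spike", "live", "like", "love", "hate", "eat",
  "drink", "experience")

.sentence_enders <- c(".", "!", "?")

penn_to_swn <- function(pos) {
  if (is.na(pos)) return(NA_character_)
  if (startsWith(pos, "NN")) return("n")
  if (startsWith(pos, "VB")) return("v")
  if (startsWith(pos, "JJ")) return("a")
  if (pos %in% c("RB", "RBR", "RBS")) return("r")
  NA_character_
}

depluralize <- function(w) {
  if (grepl("ies$", w) && nchar(w) > 4L) return(sub("ies$", "y", w))
  if (grepl("(s|x|z|ch|sh)es$", w)) return(sub("es$", "", w))
  if (grepl("[^su]s$", w)) return(sub("s$", "", w))
  w
}

strip_ing <- function(w) {
  base <- sub("ing$", "", w)
  if (base %in% .verb_stems) return(base)
  if (paste0(base, "e") %in% .verb_stems) return(paste0(base, "e"))
  if (grepl("([b-df-hj-np-tv-z])\\1$", base)) return(sub(".$", "", base))
  base
}

strip_ed <- function(w) {
  base <- sub("ed$", "", w)
  if (base %in% .verb_stems) return(base)
  if (paste0(base, "e") %in% .verb_stems) return(paste0(base, "e"))
  if (grepl("([b-df-hj-np-tv-z])\\1$", base)) return(sub(".$", "", base))
  base
}

tag_one <- function(surface) {
  if (!grepl("[A-Za-z0-9]", surface)) {
    pos <- if (surface == ",") {
      ","
    } else if (surface %in% c(".", "!", "?")) {
      "."
    } else if (surface %in% c(":", ";", "…", "-", "–", "—")) {
      ":"
    } else if (surface %in% c("(", "[", "{")) {
      "-LRB-"
    } else if (surface %in% c(")", "]", "}")) {
      "-RRB-"
    } else {
      "SYM"
    }
    return(c(pos, surface))
  }
  if (grepl("^[0-9]+([.,][0-9]+)?$", surface)) return(c("CD", surface))
  lw <- tolower(surface)
  lemma <- unname(.lemma_irregular[lw])
  pos <- unname(.penn_closed[lw])
  if (is.na(pos)) pos <- unname(.penn_lexical[lw])
  if (!is.na(pos)) {
    if (is.na(lemma)) {
      lemma <- if (pos == "NNS") depluralize(lw) else lw
    }
    return(c(pos, lemma))
  }
  nc <- nchar(lw)
  if (grepl("ly$", lw) && nc > 3L) return(c("RB", if (is.na(lemma)) lw else lemma))
  if (grepl("ing$", lw) && nc > 4L) return(c("VBG", strip_ing(lw)))
  if (grepl("ed$", lw) && nc > 3L) return(c("VBD", strip_ed(lw)))
  if (grepl("(ous|ful|ive|ic|ical|al|able|ible|ish|less|ary)$", lw)) {
    return(c("JJ", lw))
  }
  if (grepl("[b-df-hj-np-tv-z]y$", lw) && nc >= 5L) return(c("JJ", lw))
  if (grepl("(ss|us|is)$", lw)) return(c("NN", lw))
  if (grepl("s$", lw)) {
    stem <- depluralize(lw)
    if (stem %in% .verb_stems) return(c("VBZ", stem))
    return(c("NNS", stem))
  }
  c("NN", if (is.na(lemma)) lw else lemma)
}

#' Default Penn Treebank tagging backend
#'
#' A deterministic, context-free rule/lexicon backend producing Penn
#' Treebank POS tags and lowercase lemmas. Closed-class words come from a
#' built-in lexicon; open-class words fall through suffix rules
#' (`-ly` adverb, `-ing`/`-ed` verb, adjective suffixes, plural `-s`) with
#' noun as the default category. Punctuation receives the standard Penn
#' punctuation tags and `is_word = FALSE` downstream.
#'
#' Any alternative backend can be supplied to [analyze_text()] as a
#' `list(name =, tag = function(surfaces) data.frame(pos, lemma))`.
#'
#' @return a tagging backend.
#' @examples
#' penn_backend()$tag(c("When", "tablets", "better"))
#' @export
penn_backend <- function() {
  tag <- function(surfaces) {
    m <- vapply(surfaces, tag_one, character(2))
    data.frame(pos = m[1L, ], lemma = m[2L, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(name = "penn_rules", tag = tag)
}

tokenize_text <- function(text) {
  if (!nzchar(text)) return(character())
  m <- gregexpr("[A-Za-z0-9]+(?:['’-][A-Za-z0-9]+)*|[^A-Za-z0-9\\s]",
                text, perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) return(character())
  regmatches(text, list(m))[[1L]]
}

split_sentences <- function(surfaces) {
  n <- length(surfaces)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  ender <- surfaces %in% .sentence_enders
  # a sentence closes at the last token of a run of sentence-ending marks
  breaks <- which(ender & !c(ender[-1L], FALSE))
  bounds <- unique(c(0L, breaks, n))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

#' Tokenize, sentence-split, tag and lemmatize normalized text
#'
#' Runs steps two to five of the preprocessing pipeline on already-normalized
#' text: tokenization, sentence assembly (a sentence ends at a free-standing
#' `.`, `!` or `?`), POS tagging and lemmatization through the supplied
#' backend.
#'
#' @param text normalized text (see [normalize_tweet()]).
#' @param backend tagging backend, default [penn_backend()].
#' @return list with `tokens` (data.frame `surface`, `lemma`, `pos`,
#'   `index` (0-based), `is_word`) and `sentences` (data.frame of half-open
#'   0-based token ranges `start`, `end` partitioning the tokens).
#' @export
analyze_text <- function(text, backend = penn_backend()) {
  if (is.null(backend) || !is.list(backend) || !is.function(backend$tag)) {
    stop("tagging backend not configured: expected a list(name, tag); ",
         "see penn_backend()")
  }
  surfaces <- tokenize_text(text)
  if (length(surfaces)) {
    tagged <- backend$tag(surfaces)
    tokens <- data.frame(
      surface = surfaces, lemma = tagged$lemma, pos = tagged$pos,
      index = seq_along(surfaces) - 1L,
      is_word = grepl("[A-Za-z0-9]", surfaces),
      stringsAsFactors = FALSE)
  } else {
    tokens <- data.frame(surface = character(), lemma = character(),
                         pos = character(), index = integer(),
                         is_word = logical(), stringsAsFactors = FALSE)
  }
  list(tokens = tokens, sentences = split_sentences(surfaces))
}

#' Preprocess a raw tweet end to end
#'
#' Chains [normalize_tweet()] and [analyze_text()] into the full
#' preprocessing pipeline, producing a `tweet` object carrying the raw text,
#' the normalized text, the edit log, the token table and the sentence
#' spans.
#'
#' @param id tweet identifier (nonempty string).
#' @param text raw tweet text.
#' @inheritParams normalize_tweet
#' @param backend tagging backend, default [penn_backend()].
#' @return a `tweet` object.
#' @examples
#' tw <- preprocess_tweet("t1", "glucose tablets might be a better option")
#' tw$tokens
#' @export
preprocess_tweet <- function(id, text, dicts = list(),
                             corrector = corrector_noop(),
                             backend = penn_backend()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  norm <- normalize_tweet(text, dicts = dicts, corrector = corrector)
  an <- analyze_text(norm$text, backend = backend)
  structure(list(id = id, raw_text = text, normalized_text = norm$text,
                 tokens = an$tokens, sentences = an$sentences,
                 edit_log = norm$edit_log),
            class = "tweet")
}

#' Preprocess a whole corpus
#' @param tweets data.frame with `id` and `text` (see [read_tweets()]).
#' @inheritParams preprocess_tweet
#' @return named list of `tweet` objects (names = tweet ids).
#' @export
preprocess_corpus <- function(tweets, dicts = list(),
                              corrector = corrector_noop(),
                              backend = penn_backend()) {
  out <- lapply(seq_len(nrow(tweets)), function(i) {
    preprocess_tweet(tweets$id[[i]], tweets$text[[i]], dicts = dicts,
                     corrector = corrector, backend = backend)
  })
  names(out) <- tweets$id
  out
}

#' @export
print.tweet <- function(x, ...) {
  cat("<tweet ", x$id, "> ", x$normalized_text, "\n", sep = "")
  cat(paste0(x$tokens$surface, "/", x$tokens$pos, "/", x$tokens$lemma,
             collapse = " "), "\n")
  cat(nrow(x$tokens), "tokens,", nrow(x$sentences), "sentence(s)\n")
  invisible(x)
}
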