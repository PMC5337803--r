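#' Assign a polarity label to an aggregate score triple
#'
#' The decision rule is strict: an aspect is *positive* when its aggregate
#' positive score strictly exceeds both the negative and the neutral score;
#' *negative* and *neutral* are symmetric. Any tie for the maximum —
#' including the empty-window triple (0, 0, 0) — is labelled neutral, which
#' keeps the rule total over all nonnegative triples.
#'
#' @param triple numeric vector of three nonnegative aggregates
#'   (pos, neg, neu), or a list with those names.
#' @return `"positive"`, `"negative"` or `"neutral"`.
#' @examples
#' classify_polarity(c(0.875, 0, 0.125))
#' classify_polarity(c(0, 0, 0))
#' @export
classify_polarity <- function(triple) {
  if (is.list(triple)) triple <- c(triple$pos, triple$neg, triple$neu)
  stopifnot(length(triple) == 3L, is.numeric(triple))
  if (any(is.na(triple)) || any(triple < 0)) {
    stop("score triple must be three nonnegative numbers")
  }
  p <- triple[[1L]]; ng <- triple[[2L]]; nu <- triple[[3L]]
  if (p > ng && p > nu) return("positive")
  if (ng > p && ng > nu) return("negative")
  if (nu > p && nu > ng) return("neutral")
  "neutral"  # ties are undecidable under the strict rule; default neutral
}

#' Score an aspect from its context window
#'
#' For every word in the context window, a sense is selected with
#' [select_sense()]; its (pos, neg, neu) triple is the word's contribution
#' (a word with no mappable POS or no lexicon sense contributes (0, 0, 0)).
#' The aspect's aggregate triple is the element-wise sum of the
#' contributions, and the polarity label follows [classify_polarity()].
#'
#' @param window a [extract_window()] context window.
#' @param tweet the `tweet` the window was extracted from.
#' @param lexicon a [load_lexicon()] lexicon.
#' @param selector sense selector, default [selector_first_sense()].
#' @return an `aspect_sentiment` object: the aggregate `pos`, `neg`, `neu`,
#'   the `label`, and `per_word` (data.frame `token_index`, `synset_id`,
#'   `pos`, `neg`, `neu` of each contribution).
#' @export
score_aspect <- function(window, tweet, lexicon,
                         selector = selector_first_sense()) {
  stopifnot(inherits(window, "context_window"), inherits(tweet, "tweet"))
  if (!identical(window$tweet_id, tweet$id)) {
    stop("window belongs to tweet ", window$tweet_id, ", not ", tweet$id)
  }
  idx <- window$token_indices
  per_word <- data.frame(token_index = integer(), synset_id = character(),
                         pos = numeric(), neg = numeric(), neu = numeric(),
                         stringsAsFactors = FALSE)
  for (i in idx) {
    tok <- tweet$tokens[tweet$tokens$index == i, , drop = FALSE]
    entry <- select_sense(tok$lemma, tok$pos, lexicon, selector)
    per_word <- rbind(per_word, data.frame(
      token_index = i,
      synset_id = if (is.null(entry)) NA_character_ else entry$synset_id,
      pos = if (is.null(entry)) 0 else entry$pos,
      neg = if (is.null(entry)) 0 else entry$neg,
      neu = if (is.null(entry)) 0 else entry$neu,
      stringsAsFactors = FALSE))
  }
  triple <- c(sum(per_word$pos), sum(per_word$neg), sum(per_word$neu))
  structure(list(tweet_id = tweet$id, aspect = window$aspect,
                 method = window$method, n = window$n,
                 pos = triple[[1L]], neg = triple[[2L]], neu = triple[[3L]],
                 label = classify_polarity(triple), per_word = per_word),
            class = "aspect_sentiment")
}

#' @export
print.aspect_sentiment <- function(x, ...) {
  cat(sprintf("<aspect_sentiment %s [%d,%d) %s n=%d> pos=%.3f neg=%.3f neu=%.3f -> %s\n",
              x$tweet_id, x$aspect$start, x$aspect$end, x$method, x$n,
              x$pos, x$neg, x$neu, x$label))
  invisible(x)
}

#' Annotate a corpus with aspect-level sentiment
#'
#' Runs aspect detection, window extraction and scoring over a list of
#' preprocessed tweets and returns one row per detected aspect mention.
#'
#' @param tweets named list of `tweet` objects ([preprocess_corpus()]).
#' @param gazetteer a [build_gazetteer()] gazetteer.
#' @param lexicon a [load_lexicon()] lexicon.
#' @param method window method (`"around"`, `"before"`, `"after"`).
#' @param n window size.
#' @param selector sense selector.
#' @return data.frame: `tweet_id`, `start`, `end`, `concept_id`, `method`,
#'   `n`, `pos`, `neg`, `neu`, `label`.
#' @export
annotate_corpus <- function(tweets, gazetteer, lexicon,
                            method = "around", n = 3L,
                            selector = selector_first_sense()) {
  rows <- lapply(tweets, function(tw) {
    mentions <- detect_aspects(tw, gazetteer)
    if (!nrow(mentions)) return(NULL)
    res <- lapply(seq_len(nrow(mentions)), function(i) {
      w <- extract_window(tw, mentions[i, ], method = method, n = n)
      s <- score_aspect(w, tw, lexicon, selector)
      data.frame(tweet_id = tw$id, start = mentions$start[[i]],
                 end = mentions$end[[i]], concept_id = mentions$concept_id[[i]],
                 method = method, n = as.integer(n),
                 pos = s$pos, neg = s$neg, neu = s$neu, label = s$label,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(tweet_id = character(), start = integer(),
                      end = integer(), concept_id = character(),
                      method = character(), n = integer(), pos = numeric(),
                      neg = numeric(), neu = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
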