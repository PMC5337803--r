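#' Extract an N-gram context window around an aspect
#'
#' Selects the context word set for an aspect mention by one of three
#' proximity methods: `before` takes up to `n` word tokens immediately
#' preceding the mention, `after` up to `n` word tokens immediately
#' following it, and `around` the union of both (so up to `2n` tokens).
#' Punctuation tokens (`is_word = FALSE`) are skipped and do not count
#' against `n`; windows are truncated at the tweet boundaries, never cross
#' tweets, but do cross sentence boundaries. The aspect's own tokens are
#' always excluded; for multiword aspects `before` anchors at the first
#' token of the span and `after` at the last.
#'
#' @param tweet a `tweet` object.
#' @param aspect one mention: a list or one-row data.frame with `start` and
#'   `end` (0-based, half-open token span), e.g. a row of
#'   [detect_aspects()] output.
#' @param method `"before"`, `"after"` or `"around"`.
#' @param n window size, a positive integer (the pipeline default range is
#'   2 to 6).
#' @return a `context_window` object with the ordered 0-based
#'   `token_indices` of the selected words.
#' @export
extract_window <- function(tweet, aspect, method = c("around", "before", "after"),
                           n) {
  method <- match.arg(method)
  stopifnot(inherits(tweet, "tweet"), length(n) == 1L, n >= 1L)
  n <- as.integer(n)
  start <- as.integer(aspect$start)
  end <- as.integer(aspect$end)
  ntok <- nrow(tweet$tokens)
  if (is.na(start) || is.na(end) || start < 0L || end <= start || end > ntok) {
    stop("aspect span [", start, ", ", end, ") out of range for a tweet of ",
         ntok, " tokens")
  }
  word_idx <- tweet$tokens$index[tweet$tokens$is_word]
  before <- tail(word_idx[word_idx < start], n)
  after <- head(word_idx[word_idx >= end], n)
  idx <- switch(method,
                before = before,
                after = after,
                around = c(before, after))
  structure(list(tweet_id = tweet$id, aspect = as.list(aspect),
                 method = method, n = n,
                 token_indices = as.integer(idx)),
            class = "context_window")
}

#' @export
print.context_window <- function(x, ...) {
  cat("<context_window ", x$method, " n=", x$n, "> tokens [",
      paste(x$token_indices, collapse = ", "), "]\n", sep = "")
  invisible(x)
}
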