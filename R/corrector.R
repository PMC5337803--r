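#' Spell correctors
#'
#' Spell correction is a pluggable stage of [normalize_tweet()]. A corrector
#' is a list with a `name` and a `correct(word)` function returning either a
#' replacement string or `NA_character_` to leave the word untouched.
#'
#' `corrector_noop()` never changes anything and is the default, so the
#' package has no external spell-check dependency.
#'
#' `corrector_dictionary()` corrects a word only when it is absent from the
#' supplied word list and some dictionary word lies within `max_distance`
#' edits (Levenshtein, via [utils::adist()]). Among candidates at the minimal
#' distance the lexicographically first is chosen, so the corrector is fully
#' deterministic.
#'
#' @param words character vector of known (correct) words.
#' @param max_distance maximum edit distance for a correction (default 1).
#' @return a `spell_corrector` object.
#' @export
corrector_noop <- function() {
  structure(list(name = "noop",
                 correct = function(word) NA_character_),
            class = "spell_corrector")
}

#' @rdname corrector_noop
#' @export
corrector_dictionary <- function(words, max_distance = 1L) {
  words <- sort(unique(tolower(words)))
  if (!length(words)) stop("corrector_dictionary needs at least one word")
  correct <- function(word) {
    lw <- tolower(word)
    if (lw %in% words) return(NA_character_)
    d <- as.integer(adist(lw, words))
    dmin <- min(d)
    if (dmin > max_distance) return(NA_character_)
    words[which(d == dmin)][[1L]]  # words sorted: first = lexicographic tie-break
  }
  structure(list(name = "dictionary", correct = correct),
            class = "spell_corrector")
}
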