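#' Load a SentiWordNet 3.0 format sentiment lexicon
#'
#' Parses the standard tab-separated distribution format: one synset per
#' line with columns POS category (`a`/`n`/`r`/`v`), 8-digit synset ID,
#' PosScore, NegScore, SynsetTerms (space-separated `lemma#rank` pairs) and
#' Gloss. `#`-prefixed comment lines are skipped. The neutral (objective)
#' score is always recomputed as `1 - PosScore - NegScore`, so every sense's
#' (pos, neg, neu) triple sums to exactly 1; a line with PosScore + NegScore
#' exceeding 1 is a format error.
#'
#' @param path lexicon file path.
#' @return a `sentiment_lexicon` with entries keyed by (POS category,
#'   synset ID) and a (lemma, category) index ordered by sense rank.
#' @examples
#' f <- system.file("extdata", "swn-fixture.txt", package = "aspectsent")
#' lex <- load_lexicon(f)
#' lex$n_entries
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- new.env(parent = emptyenv(), hash = TRUE)
  by_lemma <- new.env(parent = emptyenv(), hash = TRUE)
  n_entries <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 5L) {
      stop("malformed lexicon line ", ln, ": expected >= 5 tab-separated ",
           "columns (POS, ID, PosScore, NegScore, SynsetTerms[, Gloss])")
    }
    pos_cat <- parts[[1L]]
    if (!pos_cat %in% c("a", "n", "r", "v")) {
      stop("malformed lexicon line ", ln, ": POS category ",
           dQuote(pos_cat), " not one of a/n/r/v")
    }
    synset_id <- parts[[2L]]
    if (!grepl("^[0-9]{8}$", synset_id)) {
      stop("malformed lexicon line ", ln, ": synset ID ",
           dQuote(synset_id), " is not 8 digits")
    }
    pos <- suppressWarnings(as.numeric(parts[[3L]]))
    neg <- suppressWarnings(as.numeric(parts[[4L]]))
    if (is.na(pos) || is.na(neg) || pos < 0 || neg < 0) {
      stop("malformed lexicon line ", ln, ": non-numeric or negative score")
    }
    if (pos + neg > 1 + 1e-9) {
      stop("malformed lexicon line ", ln, ": PosScore + NegScore = ",
           pos + neg, " exceeds 1")
    }
    term_field <- strsplit(trimws(parts[[5L]]), " +")[[1L]]
    term_field <- term_field[nzchar(term_field)]
    if (!length(term_field)) {
      stop("malformed lexicon line ", ln, ": empty SynsetTerms")
    }
    lemmas <- sub("#[0-9]+$", "", term_field)
    ranks <- suppressWarnings(as.integer(sub("^.*#", "", term_field)))
    if (any(is.na(ranks))) {
      stop("malformed lexicon line ", ln, ": SynsetTerms must be lemma#rank")
    }
    entry <- list(pos_category = pos_cat, synset_id = synset_id,
                  pos = pos, neg = neg, neu = 1 - pos - neg,
                  terms = data.frame(lemma = tolower(lemmas), rank = ranks,
                                     stringsAsFactors = FALSE),
                  gloss = if (length(parts) >= 6L) parts[[6L]] else "")
    key <- paste(pos_cat, synset_id, sep = "|")
    if (!is.null(get0(key, envir = entries, inherits = FALSE))) {
      stop("duplicate lexicon entry ", key, " at line ", ln)
    }
    assign(key, entry, envir = entries)
    n_entries <- n_entries + 1L
    for (t in seq_len(nrow(entry$terms))) {
      lkey <- paste(entry$terms$lemma[[t]], pos_cat, sep = "|")
      cur <- get0(lkey, envir = by_lemma, inherits = FALSE)
      add <- data.frame(rank = entry$terms$rank[[t]], key = key,
                        stringsAsFactors = FALSE)
      assign(lkey, rbind(cur, add), envir = by_lemma)
    }
  }
  if (n_entries == 0L) stop("lexicon has zero entries: ", path)
  structure(list(entries = entries, by_lemma = by_lemma,
                 n_entries = n_entries),
            class = "sentiment_lexicon")
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat("<sentiment_lexicon> ", x$n_entries, " synset entries\n", sep = "")
  invisible(x)
}

lexicon_entry <- function(lexicon, pos_category, synset_id) {
  get0(paste(pos_category, synset_id, sep = "|"),
       envir = lexicon$entries, inherits = FALSE)
}

#' Sense selectors
#'
#' A word may belong to many senses (synsets) of its POS category; a sense
#' selector decides which one contributes its score triple. Selectors are a
#' pluggable strategy: a list with a `name` and a
#' `select(lemma, category, candidates)` function, where `candidates` is a
#' list of lexicon entries ordered by sense rank, returning one entry. The
#' default, `selector_first_sense()`, is the standard most-frequent-sense
#' baseline: it picks the sense with the smallest rank (ties on rank broken
#' by the smaller synset ID), which keeps the whole pipeline deterministic
#' and offline. A disambiguation-service adapter can be plugged in through
#' the same contract.
#'
#' @return a `sense_selector`.
#' @export
selector_first_sense <- function() {
  structure(list(
    name = "first_sense",
    select = function(lemma, category, candidates) candidates[[1L]]),
    class = "sense_selector")
}

#' Select the lexicon sense for a (lemma, Penn tag) pair
#'
#' Maps the Penn Treebank tag to a lexicon POS category (`NN*` to n, `VB*`
#' to v, `JJ*` to a, `RB`/`RBR`/`RBS` to r; anything else is unmappable),
#' gathers the candidate senses for the lemma in that category ordered by
#' sense rank, and delegates the choice to the selector. `NULL` is returned
#' when the tag is unmappable or the lemma is absent: absence is a valid
#' outcome, not an error, and contributes a zero triple downstream.
#'
#' @param lemma lowercase lemma.
#' @param penn_pos Penn Treebank tag.
#' @param lexicon a [load_lexicon()] object.
#' @param selector a sense selector, default [selector_first_sense()].
#' @return a lexicon entry (list with `pos`, `neg`, `neu`, `synset_id`,
#'   ...) or `NULL`.
#' @export
select_sense <- function(lemma, penn_pos, lexicon,
                         selector = selector_first_sense()) {
  category <- penn_to_swn(penn_pos)
  if (is.na(category)) return(NULL)
  cand <- get0(paste(tolower(lemma), category, sep = "|"),
               envir = lexicon$by_lemma, inherits = FALSE)
  if (is.null(cand) || !nrow(cand)) return(NULL)
  cand <- cand[order(cand$rank, cand$key), , drop = FALSE]
  candidates <- lapply(cand$key, function(k) {
    get0(k, envir = lexicon$entries, inherits = FALSE)
  })
  selector$select(tolower(lemma), category, candidates)
}
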