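#' Build a concept gazetteer
#'
#' A gazetteer maps lemmatized term sequences to concept identifiers and is
#' the aspect vocabulary of the pipeline. The canonical source is a flat
#' 2-column TSV (`concept_id <TAB> term`, one term variant per row,
#' `#`-comments allowed); [owl_to_gazetteer()] converts an OWL ontology's
#' labels/synonyms into that format, so the core pipeline never parses OWL
#' at runtime.
#'
#' Each term is tokenized, lowercased and lemmatized with the tagging
#' backend, so matching later happens on lemma sequences ("glucose tablets"
#' matches a "glucose tablet" term). Duplicate (term, concept) rows are
#' collapsed; a term claimed by several concepts is resolved to the
#' lexicographically smallest `concept_id` with a build warning. The build
#' report (term/concept counts, collisions) is attached as attribute
#' `report`.
#'
#' @param source path to a gazetteer TSV, or a data.frame with columns
#'   `concept_id` and `term`.
#' @param backend tagging backend used to lemmatize terms.
#' @return a `gazetteer` object.
#' @examples
#' g <- build_gazetteer(data.frame(concept_id = "DDO:0001",
#'                                 term = "blood sugar"))
#' @export
build_gazetteer <- function(source, backend = penn_backend()) {
  if (is.character(source)) {
    source <- read_gazetteer_tsv(source)
  }
  if (!is.data.frame(source) || !all(c("concept_id", "term") %in% names(source))) {
    stop("gazetteer source must be a TSV path or a data.frame with ",
         "'concept_id' and 'term' columns")
  }
  source <- source[nzchar(trimws(source$term)), , drop = FALSE]
  if (!nrow(source)) stop("gazetteer has zero terms")

  keys <- vapply(source$term, function(term) {
    an <- analyze_text(tolower(term), backend = backend)
    lemmas <- an$tokens$lemma[an$tokens$is_word]
    if (!length(lemmas)) return(NA_character_)
    paste(lemmas, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  ok <- !is.na(keys)
  source <- source[ok, , drop = FALSE]
  keys <- keys[ok]
  if (!length(keys)) stop("gazetteer has zero terms")

  df <- unique(data.frame(key = keys, concept_id = source$concept_id,
                          term = source$term, stringsAsFactors = FALSE))
  collisions <- character()
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in unique(df$key)) {
    ids <- sort(unique(df$concept_id[df$key == k]))
    if (length(ids) > 1L) collisions <- c(collisions, k)
    assign(k, ids[[1L]], envir = index)
  }
  if (length(collisions)) {
    warning("gazetteer term collision(s) resolved to smallest concept_id: ",
            paste(collisions, collapse = "; "))
  }
  entries <- split(df$key, df$concept_id)
  entries <- lapply(entries, function(x) strsplit(sort(unique(x)), " ", fixed = TRUE))
  report <- list(n_terms = length(unique(df$key)),
                 n_concepts = length(entries),
                 collisions = collisions)
  structure(list(entries = entries, index = index,
                 max_words = max(lengths(strsplit(df$key, " ", fixed = TRUE)))),
            report = report, class = "gazetteer")
}

#' Read a gazetteer TSV (concept_id <TAB> term)
#' @param path TSV path.
#' @export
read_gazetteer_tsv <- function(path) {
  if (!file.exists(path)) stop("gazetteer file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("gazetteer has zero terms")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) stop("malformed gazetteer line ", bad[[1L]], " in ", path)
  data.frame(concept_id = vapply(parts, `[[`, character(1), 1L),
             term = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Write a gazetteer data.frame as TSV
#' @param gaz data.frame with `concept_id`, `term`.
#' @param path output path.
#' @export
write_gazetteer_tsv <- function(gaz, path) {
  writeLines(paste(gaz$concept_id, gaz$term, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.gazetteer <- function(x, ...) {
  rep <- attr(x, "report")
  cat("<gazetteer> ", rep$n_terms, " terms, ", rep$n_concepts, " concepts",
      if (length(rep$collisions)) paste0(", ", length(rep$collisions),
                                         " collision(s)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Detect aspect mentions in an analyzed tweet
#'
#' Scans the tweet's lemma sequence against the gazetteer index. At each
#' start position the longest matching term wins; matches are non-overlapping
#' and returned in order of their start token (leftmost-longest; ties on
#' length resolved to the smaller start). Matching is case-insensitive by
#' construction (lemmas are lowercase).
#'
#' @param tweet a `tweet` object from [preprocess_tweet()].
#' @param gazetteer a [build_gazetteer()] object.
#' @return data.frame with one row per mention: `tweet_id`, `start`, `end`
#'   (0-based half-open token span), `concept_id`, `surface` (joined token
#'   surfaces), `sentence_index` (0-based sentence of the span start).
#' @export
detect_aspects <- function(tweet, gazetteer) {
  stopifnot(inherits(tweet, "tweet"), inherits(gazetteer, "gazetteer"))
  lemmas <- tweet$tokens$lemma
  n <- length(lemmas)
  rows <- list()
  i <- 1L
  while (i <= n) {
    found <- 0L
    for (len in seq(min(gazetteer$max_words, n - i + 1L), 1L)) {
      key <- paste(lemmas[i:(i + len - 1L)], collapse = " ")
      cid <- get0(key, envir = gazetteer$index, inherits = FALSE)
      if (!is.null(cid)) {
        sent <- which(tweet$sentences$start <= i - 1L &
                        tweet$sentences$end > i - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          tweet_id = tweet$id, start = i - 1L, end = i - 1L + len,
          concept_id = cid,
          surface = paste(tweet$tokens$surface[i:(i + len - 1L)],
                          collapse = " "),
          sentence_index = if (length(sent)) sent[[1L]] - 1L else NA_integer_,
          stringsAsFactors = FALSE)
        found <- len
        break
      }
    }
    i <- i + max(found, 1L)
  }
  if (!length(rows)) {
    return(data.frame(tweet_id = character(), start = integer(),
                      end = integer(), concept_id = character(),
                      surface = character(), sentence_index = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
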