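#' Read tweets from JSONL or TSV
#'
#' Accepts either JSON-lines (`{"id": ..., "text": ...}` per line) or a
#' 2-column tab-separated file (id, text; `#`-prefixed lines ignored). The
#' format is chosen from the first non-empty line.
#'
#' @param path file path.
#' @return data.frame with character columns `id` and `text`.
#' @export
read_tweets <- function(path) {
  if (!file.exists(path)) stop("tweet file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), text = character(),
                      stringsAsFactors = FALSE))
  }
  if (startsWith(trimws(lines[[1L]]), "{")) {
    recs <- lapply(lines, jsonlite::fromJSON)
    ids <- vapply(recs, function(r) as.character(r$id), character(1))
    txt <- vapply(recs, function(r) {
      if (is.null(r$text)) "" else as.character(r$text)
    }, character(1))
  } else {
    lines <- lines[!startsWith(trimws(lines), "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 0L) < 2L)
    if (length(bad)) stop("malformed TSV tweet line ", bad[[1L]])
    ids <- vapply(parts, `[[`, character(1), 1L)
    txt <- vapply(parts, function(p) paste(p[-1L], collapse = "\t"),
                  character(1))
  }
  if (any(!nzchar(ids))) stop("tweet with empty id")
  data.frame(id = ids, text = txt, stringsAsFactors = FALSE)
}

#' Write tweets as JSON lines
#' @param tweets data.frame with `id`, `text`.
#' @param path output path.
#' @export
write_tweets_jsonl <- function(tweets, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(tweets))) {
    writeLines(jsonlite::toJSON(list(id = tweets$id[[i]],
                                     text = tweets$text[[i]]),
                                auto_unbox = TRUE),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read an abbreviation dictionary
#'
#' 2-column TSV: abbreviation, expansion. Keys are matched
#' case-insensitively; `#`-prefixed comment lines are skipped. Multi-word
#' keys are allowed and matched longest-first.
#'
#' @param path TSV file path.
#' @param source tag recorded on the dictionary, `"sms"` or `"domain"`.
#'   Domain dictionaries are consulted before SMS ones during normalization.
#' @return an `abbrev_dict` object.
#' @export
read_abbreviations <- function(path, source = c("domain", "sms")) {
  source <- match.arg(source)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) stop("malformed abbreviation line ", bad[[1L]], " in ", path)
  keys <- tolower(trimws(vapply(parts, `[[`, character(1), 1L)))
  vals <- trimws(vapply(parts, `[[`, character(1), 2L))
  abbrev_dict(setNames(vals, keys), source = source)
}

#' Build an abbreviation dictionary from a named character vector
#' @param map named character vector, names are the abbreviations.
#' @param source `"sms"` or `"domain"`.
#' @export
abbrev_dict <- function(map, source = c("domain", "sms")) {
  source <- match.arg(source)
  if (length(map)) {
    names(map) <- tolower(names(map))
    if (anyDuplicated(names(map)))
      stop("duplicate abbreviation key in ", source, " dictionary")
    if (any(!nzchar(map))) stop("empty expansion in ", source, " dictionary")
  }
  structure(list(map = map, source = source,
                 max_words = if (length(map)) {
                   max(lengths(strsplit(names(map), " ", fixed = TRUE)))
                 } else 0L),
            class = "abbrev_dict")
}

#' Read gold aspect annotations (JSONL)
#'
#' Each line is `{"tweet_id": ..., "start": ..., "end": ..., "label": ...}`
#' with 0-based, half-open token spans.
#'
#' @param path JSONL file path.
#' @return data.frame `tweet_id`, `start`, `end`, `label`.
#' @export
read_gold <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(
    tweet_id = vapply(recs, function(r) as.character(r$tweet_id), character(1)),
    start = vapply(recs, function(r) as.integer(r$start), integer(1)),
    end = vapply(recs, function(r) as.integer(r$end), integer(1)),
    label = vapply(recs, function(r) as.character(r$label), character(1)),
    stringsAsFactors = FALSE)
  validate_labels(out$label)
  out
}

#' Write gold annotations as JSON lines
#' @param gold data.frame with `tweet_id`, `start`, `end`, `label`.
#' @param path output path.
#' @export
write_gold_jsonl <- function(gold, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(gold))) {
    writeLines(jsonlite::toJSON(list(tweet_id = gold$tweet_id[[i]],
                                     start = gold$start[[i]],
                                     end = gold$end[[i]],
                                     label = gold$label[[i]]),
                                auto_unbox = TRUE),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Write per-aspect sentiment annotations as JSON lines
#' @param aspects data.frame as returned by [annotate_corpus()].
#' @param path output path.
#' @export
write_aspects_jsonl <- function(aspects, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(aspects))) {
    row <- aspects[i, , drop = FALSE]
    writeLines(jsonlite::toJSON(
      list(tweet_id = row$tweet_id, span = c(row$start, row$end),
           concept_id = row$concept_id, method = row$method, n = row$n,
           pos = row$pos, neg = row$neg, neu = row$neu, label = row$label),
      auto_unbox = TRUE, digits = NA), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read per-aspect annotations written by [write_aspects_jsonl()]
#' @param path JSONL path.
#' @export
read_aspects_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    tweet_id = vapply(recs, function(r) as.character(r$tweet_id), character(1)),
    start = vapply(recs, function(r) as.integer(r$span[[1L]]), integer(1)),
    end = vapply(recs, function(r) as.integer(r$span[[2L]]), integer(1)),
    concept_id = vapply(recs, function(r) as.character(r$concept_id), character(1)),
    method = vapply(recs, function(r) as.character(r$method), character(1)),
    n = vapply(recs, function(r) as.integer(r$n), integer(1)),
    pos = vapply(recs, function(r) as.numeric(r$pos), numeric(1)),
    neg = vapply(recs, function(r) as.numeric(r$neg), numeric(1)),
    neu = vapply(recs, function(r) as.numeric(r$neu), numeric(1)),
    label = vapply(recs, function(r) as.character(r$label), character(1)),
    stringsAsFactors = FALSE)
}

validate_labels <- function(labels) {
  bad <- setdiff(unique(labels), c("positive", "negative", "neutral"))
  if (length(bad)) {
    stop("invalid polarity label(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
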