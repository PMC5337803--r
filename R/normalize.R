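#' Normalize a raw tweet
#'
#' Applies, in order: (1) removal of whole `@`-mention tokens; (2) removal of
#' URL tokens (`http://`, `https://`, bare `t.co/` shorteners); (3) removal
#' of the `#` character of hashtags, keeping the hashtag body; (4) whitespace
#' normalization; (5) case-insensitive, token-based abbreviation expansion
#' (domain dictionaries consulted before SMS ones, longest key wins); (6)
#' spell correction of the remaining words through a pluggable corrector.
#'
#' Every edit is recorded with its type, 0-based character offset into the
#' text as it stood when the edit was applied, the original substring and its
#' replacement, so [apply_edit_log()] replays the log exactly.
#'
#' @param text raw tweet text (may be empty).
#' @param dicts list of [abbrev_dict()] objects.
#' @param corrector a [corrector_noop()]-style spell corrector.
#' @return list with `text` (normalized string) and `edit_log` (data.frame
#'   with columns `type`, `start`, `original`, `replacement`).
#' @examples
#' d <- abbrev_dict(c(carbs = "carbohydrates"), source = "domain")
#' normalize_tweet("@user1 my carbs spiked http://t.co/xyz #diabetes",
#'                 dicts = list(d))$text
#' @export
normalize_tweet <- function(text, dicts = list(), corrector = corrector_noop()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) text <- ""
  if (length(dicts) && inherits(dicts, "abbrev_dict")) dicts <- list(dicts)
  for (d in dicts) {
    if (!inherits(d, "abbrev_dict")) stop("dicts must be abbrev_dict objects")
  }
  if (!inherits(corrector, "spell_corrector")) {
    stop("corrector must be a spell_corrector (see corrector_noop())")
  }
  # domain dictionaries take precedence over SMS ones
  ord <- order(vapply(dicts, function(d) d$source != "domain", logical(1)))
  dicts <- dicts[ord]

  st <- list(text = text, log = list())

  st <- remove_pattern(st, "(?:^|(?<=\\s))@\\S+ ?", "mention")
  st <- remove_pattern(st, "(?:^|(?<=\\s))\\S*(?:https?://|\\bt\\.co/)\\S* ?", "url")
  st <- remove_pattern(st, "#", "hashtag")
  st <- normalize_whitespace(st)
  st <- expand_abbreviations(st, dicts)
  st <- correct_spelling(st, dicts, corrector)
  st <- normalize_whitespace(st)

  log <- if (length(st$log)) {
    do.call(rbind, st$log)
  } else {
    data.frame(type = character(), start = integer(), original = character(),
               replacement = character(), stringsAsFactors = FALSE)
  }
  rownames(log) <- NULL
  list(text = st$text, edit_log = log)
}

#' Replay an edit log
#'
#' Applies the edits recorded by [normalize_tweet()] to the original raw
#' text, reproducing the normalized text exactly.
#'
#' @param text the raw text the log was produced from.
#' @param edit_log the `edit_log` data.frame.
#' @export
apply_edit_log <- function(text, edit_log) {
  for (i in seq_len(nrow(edit_log))) {
    text <- splice(text, edit_log$start[[i]], edit_log$original[[i]],
                   edit_log$replacement[[i]])
  }
  text
}

# replace `original` at 0-based offset `start` with `replacement`,
# verifying the text actually carries `original` there
splice <- function(s, start, original, replacement) {
  n <- nchar(original)
  have <- substr(s, start + 1L, start + n)
  if (!identical(have, original)) {
    stop("edit log does not match text at offset ", start,
         ": expected ", dQuote(original), ", found ", dQuote(have))
  }
  paste0(substr(s, 1L, start), replacement,
         substr(s, start + n + 1L, nchar(s)))
}

record_edit <- function(st, type, start, original, replacement) {
  st$log[[length(st$log) + 1L]] <- data.frame(
    type = type, start = as.integer(start), original = original,
    replacement = replacement, stringsAsFactors = FALSE)
  st$text <- splice(st$text, start, original, replacement)
  st
}

remove_pattern <- function(st, pattern, type) {
  repeat {
    m <- regexpr(pattern, st$text, perl = TRUE)
    if (m == -1L) break
    start <- as.integer(m) - 1L
    orig <- substr(st$text, m, m + attr(m, "match.length") - 1L)
    st <- record_edit(st, type, start, orig, "")
  }
  st
}

normalize_whitespace <- function(st) {
  # unify exotic whitespace, collapse runs, trim both ends
  st <- replace_pattern(st, "[\\t\\r\\n]", "whitespace", " ")
  st <- replace_pattern(st, " {2,}", "whitespace", " ")
  st <- replace_pattern(st, "^ +| +$", "whitespace", "")
  st
}

replace_pattern <- function(st, pattern, type, replacement) {
  repeat {
    m <- regexpr(pattern, st$text, perl = TRUE)
    if (m == -1L) break
    start <- as.integer(m) - 1L
    orig <- substr(st$text, m, m + attr(m, "match.length") - 1L)
    if (identical(orig, replacement)) break
    st <- record_edit(st, type, start, orig, replacement)
  }
  st
}

word_positions <- function(s) {
  m <- gregexpr("[A-Za-z0-9]+(?:['’-][A-Za-z0-9]+)*", s, perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) {
    return(data.frame(start = integer(), len = integer(), word = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(start = as.integer(m) - 1L, len = attr(m, "match.length"),
             word = regmatches(s, list(m))[[1L]], stringsAsFactors = FALSE)
}

expand_abbreviations <- function(st, dicts) {
  if (!length(dicts)) return(st)
  max_words <- max(vapply(dicts, function(d) d$max_words, 0L))
  if (max_words == 0L) return(st)
  from <- 0L  # character offset below which the text is final (incl. expansions)
  repeat {
    wp <- word_positions(st$text)
    wp <- wp[wp$start >= from, , drop = FALSE]
    if (!nrow(wp)) break
    hit <- NULL
    for (i in seq_len(nrow(wp))) {
      for (len in seq(min(max_words, nrow(wp) - i + 1L), 1L)) {
        key <- tolower(paste(wp$word[i:(i + len - 1L)], collapse = " "))
        for (d in dicts) {
          exp <- unname(d$map[key])
          if (!is.na(exp)) {
            hit <- list(start = wp$start[[i]],
                        end = wp$start[[i + len - 1L]] + wp$len[[i + len - 1L]],
                        expansion = exp)
            break
          }
        }
        if (!is.null(hit)) break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    orig <- substr(st$text, hit$start + 1L, hit$end)
    st <- record_edit(st, "abbreviation", hit$start, orig, hit$expansion)
    from <- hit$start + nchar(hit$expansion)  # never rescan the expansion
  }
  st
}

correct_spelling <- function(st, dicts, corrector) {
  expansions <- tolower(unlist(lapply(dicts, function(d) unname(d$map))))
  expansion_words <- unique(unlist(strsplit(expansions, " ", fixed = TRUE)))
  from <- 0L
  repeat {
    wp <- word_positions(st$text)
    wp <- wp[wp$start >= from, , drop = FALSE]
    if (!nrow(wp)) break
    changed <- FALSE
    for (i in seq_len(nrow(wp))) {
      w <- wp$word[[i]]
      from <- wp$start[[i]] + wp$len[[i]]
      if (!grepl("^[A-Za-z]+$", w)) next
      if (tolower(w) %in% expansion_words) next
      repl <- corrector$correct(w)
      if (!is.na(repl) && !identical(repl, w)) {
        st <- record_edit(st, "spelling", wp$start[[i]], w, repl)
        from <- wp$start[[i]] + nchar(repl)
        changed <- TRUE
        break  # offsets shifted; re-tokenize
      }
    }
    if (!changed) break
  }
  st
}
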