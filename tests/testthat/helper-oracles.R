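# Brute-force reference implementations, kept deliberately flat and
# index-free so they stay independent of the package's production paths.

# every subspan of the token sequence is checked against the term index;
# overlaps resolved leftmost-longest, exactly the documented contract
oracle_detect <- function(tweet, gazetteer) {
  lemmas <- tweet$tokens$lemma
  n <- length(lemmas)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      key <- paste(lemmas[i:j], collapse = " ")
      cid <- get0(key, envir = gazetteer$index, inherits = FALSE)
      if (!is.null(cid)) {
        hits[[length(hits) + 1L]] <- c(start = i - 1L, end = j, len = j - i + 1L)
      }
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  h <- as.data.frame(do.call(rbind, hits))
  h <- h[order(h$start, -h$len), ]
  chosen <- list()
  next_free <- 0L  # leftmost-longest, non-overlapping
  for (r in seq_len(nrow(h))) {
    if (h$start[[r]] >= next_free) {
      chosen[[length(chosen) + 1L]] <- h[r, c("start", "end")]
      next_free <- h$end[[r]]
    }
  }
  out <- do.call(rbind, chosen)
  rownames(out) <- NULL
  out
}

# window by plain index filtering, no truncation shortcuts
oracle_window <- function(tweet, aspect, method, n) {
  words <- tweet$tokens$index[tweet$tokens$is_word]
  before <- words[words < aspect$start]
  if (length(before) > n) before <- before[(length(before) - n + 1L):length(before)]
  after <- words[words >= aspect$end]
  if (length(after) > n) after <- after[1:n]
  switch(method, before = before, after = after, around = c(before, after))
}

# flat accumulator over window words
oracle_score_triple <- function(tweet, indices, lexicon,
                                selector = selector_first_sense()) {
  total <- c(0, 0, 0)
  for (i in indices) {
    tok <- tweet$tokens[tweet$tokens$index == i, ]
    entry <- select_sense(tok$lemma, tok$pos, lexicon, selector)
    if (!is.null(entry)) total <- total + c(entry$pos, entry$neg, entry$neu)
  }
  total
}

# confusion-matrix polarity metrics, written independently of eval_polarity
oracle_polarity_prf <- function(pred_labels, gold_labels) {
  classes <- intersect(c("positive", "negative", "neutral"),
                       union(gold_labels, pred_labels))
  p <- r <- f <- numeric(0)
  for (cl in classes) {
    tp <- sum(pred_labels == cl & gold_labels == cl)
    fp <- sum(pred_labels == cl & gold_labels != cl)
    fn <- sum(pred_labels != cl & gold_labels == cl)
    pc <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    fc <- if (pc + rc > 0) 2 * pc * rc / (pc + rc) else 0
    p <- c(p, pc); r <- c(r, rc); f <- c(f, fc)
  }
  list(macro_p = mean(p), macro_r = mean(r), macro_f = mean(f))
}

# build a lexicon object from raw SWN-format lines through the file parser
lexicon_from_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  load_lexicon(f)
}

fixture_lexicon <- function() {
  load_lexicon(system.file("extdata", "swn-fixture.txt",
                           package = "aspectsent"))
}

fixture_gazetteer <- function() {
  build_gazetteer(system.file("extdata", "gazetteer-fixture.tsv",
                              package = "aspectsent"))
}

# full pipeline macro-F at one (method, n) cell for a synthetic corpus
pipeline_macro_f <- function(corpus, method = "around", n = 3L) {
  lex <- corpus_lexicon(corpus)
  gaz <- build_gazetteer(corpus$gazetteer)
  pred <- annotate_corpus(corpus$analyzed, gaz, lex, method = method, n = n)
  ev <- suppressWarnings(eval_polarity(pred, corpus$gold))
  ev$macro$f_measure
}
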