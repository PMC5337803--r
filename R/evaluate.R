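#' Precision / recall / F-measure from match counts
#'
#' Precision = 100 * TP / (TP + FP), recall = 100 * TP / (TP + FN), and the
#' F-measure is their harmonic mean, all reported as percentages. A zero
#' denominator yields 0 with a warning rather than NaN, so sweeps over many
#' configurations never crash on a degenerate cell.
#'
#' @param tp,fp,fn nonnegative integer counts.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f_measure`.
#' @examples
#' prf_counts(3, 1, 2)  # P = 75, R = 60, F = 66.67
#' @export
prf_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
    warning("precision undefined (no predictions); reporting 0")
    0
  }
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("recall undefined (no gold items); reporting 0")
    0
  }
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
       precision = precision, recall = recall,
       f_measure = f_measure(precision, recall))
}

#' Harmonic mean of precision and recall
#' @param precision,recall percentages in \[0, 100].
#' @return the F-measure percentage (0 when both inputs are 0).
#' @examples
#' f_measure(85.71, 80.00)  # 82.75 after rounding to 2 decimals
#' @export
f_measure <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

span_key <- function(df) paste(df$tweet_id, df$start, df$end, sep = "\r")

#' Evaluate aspect identification against gold spans
#'
#' Matches predicted mentions to gold annotations one-to-one. In `exact`
#' mode a true positive requires an identical (tweet, start, end) token
#' span. In `overlap` mode spans sharing at least one token match, paired
#' greedily leftmost-first within each tweet. Unmatched predictions are
#' false positives and unmatched gold spans false negatives.
#'
#' @param pred data.frame of predicted mentions (`tweet_id`, `start`, `end`).
#' @param gold data.frame of gold annotations (`tweet_id`, `start`, `end`).
#'   Duplicate gold spans within a tweet are a validation error.
#' @param mode `"exact"` (default) or `"overlap"`.
#' @return a [prf_counts()] result.
#' @export
eval_identification <- function(pred, gold, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  if (anyDuplicated(span_key(gold))) {
    stop("duplicate gold span(s) within a tweet")
  }
  pairs <- match_spans(pred, gold, mode)
  prf_counts(tp = nrow(pairs), fp = nrow(pred) - nrow(pairs),
             fn = nrow(gold) - nrow(pairs))
}

# greedy 1-to-1 matching; returns data.frame(pred_row, gold_row)
match_spans <- function(pred, gold, mode) {
  out <- data.frame(pred_row = integer(), gold_row = integer())
  if (!nrow(pred) || !nrow(gold)) return(out)
  if (mode == "exact") {
    gkey <- span_key(gold)
    taken <- rep(FALSE, nrow(gold))
    for (i in order(pred$tweet_id, pred$start)) {
      j <- which(gkey == span_key(pred[i, ]) & !taken)
      if (length(j)) {
        taken[j[[1L]]] <- TRUE
        out <- rbind(out, data.frame(pred_row = i, gold_row = j[[1L]]))
      }
    }
  } else {
    taken <- rep(FALSE, nrow(gold))
    for (i in order(pred$tweet_id, pred$start)) {
      j <- which(gold$tweet_id == pred$tweet_id[[i]] & !taken &
                   pmax(gold$start, pred$start[[i]]) <
                     pmin(gold$end, pred$end[[i]]))
      if (length(j)) {
        j <- j[order(gold$start[j])][[1L]]  # leftmost gold first
        taken[j] <- TRUE
        out <- rbind(out, data.frame(pred_row = i, gold_row = j))
      }
    }
  }
  out
}

#' Evaluate aspect-level polarity against gold labels
#'
#' Restricts evaluation to aspects matched by [eval_identification()]'s
#' criterion (same `mode`), then scores the 3-class polarity decision. Each
#' label is treated one-vs-rest: per-class precision, recall and F are
#' computed from the confusion counts; the `macro` average is the unweighted
#' mean of the per-class P, R and F over the classes present in gold or
#' predictions, while `micro` pools the counts (for single-label decisions
#' micro P = R = F = accuracy on the matched aspects).
#'
#' @param pred data.frame with `tweet_id`, `start`, `end`, `label`
#'   (e.g. [annotate_corpus()] output).
#' @param gold data.frame with `tweet_id`, `start`, `end`, `label`.
#' @param averaging `"macro"` (default) or `"micro"` for the overall block;
#'   both are always available in the result.
#' @param mode span-matching criterion, as in [eval_identification()].
#' @return list with `overall` (P/R/F for the requested averaging),
#'   `macro`, `micro`, `per_class` (data.frame), and `n_matched`.
#' @export
eval_polarity <- function(pred, gold, averaging = c("macro", "micro"),
                          mode = c("exact", "overlap")) {
  averaging <- match.arg(averaging)
  mode <- match.arg(mode)
  validate_labels(gold$label)
  validate_labels(pred$label)
  pairs <- match_spans(pred, gold, mode)
  if (!nrow(pairs)) {
    warning("no identification-matched aspects; polarity metrics are 0")
    zero <- list(precision = 0, recall = 0, f_measure = 0)
    return(list(overall = zero, macro = zero, micro = zero,
                per_class = data.frame(class = character(), tp = integer(),
                                       fp = integer(), fn = integer(),
                                       precision = numeric(), recall = numeric(),
                                       f_measure = numeric(),
                                       stringsAsFactors = FALSE),
                n_matched = 0L))
  }
  p_lab <- pred$label[pairs$pred_row]
  g_lab <- gold$label[pairs$gold_row]
  classes <- intersect(c("positive", "negative", "neutral"),
                       union(g_lab, p_lab))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(p_lab == cl & g_lab == cl)
    fp <- sum(p_lab == cl & g_lab != cl)
    fn <- sum(p_lab != cl & g_lab == cl)
    r <- suppressWarnings(prf_counts(tp, fp, fn))
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = r$precision, recall = r$recall,
               f_measure = r$f_measure, stringsAsFactors = FALSE)
  }))
  macro <- list(precision = mean(per_class$precision),
                recall = mean(per_class$recall),
                f_measure = mean(per_class$f_measure))
  micro_r <- suppressWarnings(
    prf_counts(sum(per_class$tp), sum(per_class$fp), sum(per_class$fn)))
  micro <- micro_r[c("precision", "recall", "f_measure")]
  list(overall = if (averaging == "macro") macro else micro,
       macro = macro, micro = micro, per_class = per_class,
       n_matched = nrow(pairs))
}

#' Sweep window methods and sizes over a corpus
#'
#' Runs the full pipeline (aspect detection, window extraction, scoring)
#' for every combination of window method and window size, evaluating the
#' polarity decisions against gold annotations, and reports one cell per
#' (method, n) plus a single aspect-identification result. Deterministic
#' for fixed inputs.
#'
#' @param tweets named list of `tweet` objects.
#' @param gold gold annotations (`tweet_id`, `start`, `end`, `label`).
#' @param lexicon a [load_lexicon()] lexicon.
#' @param gazetteer a [build_gazetteer()] gazetteer.
#' @param methods window methods to cover.
#' @param n_values window sizes to cover (default 2 to 6).
#' @param selector sense selector.
#' @param mode span-matching criterion for evaluation.
#' @return a `sweep_report`: data.frame `cells` with columns `method`, `n`,
#'   `macro_p`, `macro_r`, `macro_f`, `micro_p`, `micro_r`, `micro_f`,
#'   `n_matched`, plus attribute `identification` (a [prf_counts()] result).
#' @export
run_sweep <- function(tweets, gold, lexicon, gazetteer,
                      methods = c("before", "after", "around"),
                      n_values = 2:6, selector = selector_first_sense(),
                      mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  mentions <- lapply(tweets, detect_aspects, gazetteer = gazetteer)
  pred_spans <- do.call(rbind, c(mentions, list(make.row.names = FALSE)))
  if (is.null(pred_spans)) {
    pred_spans <- data.frame(tweet_id = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
  }
  identification <- suppressWarnings(
    eval_identification(pred_spans, gold, mode = mode))
  cells <- list()
  for (method in methods) {
    for (n in n_values) {
      pred <- annotate_corpus(tweets, gazetteer, lexicon,
                              method = method, n = n, selector = selector)
      ev <- suppressWarnings(eval_polarity(pred, gold, mode = mode))
      cells[[length(cells) + 1L]] <- data.frame(
        method = method, n = as.integer(n),
        macro_p = ev$macro$precision, macro_r = ev$macro$recall,
        macro_f = ev$macro$f_measure,
        micro_p = ev$micro$precision, micro_r = ev$micro$recall,
        micro_f = ev$micro$f_measure,
        n_matched = ev$n_matched, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(cells = cells, identification = identification),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, digits = 2, ...) {
  id <- x$identification
  cat(sprintf("Aspect identification: P = %.2f, R = %.2f, F = %.2f (tp=%d fp=%d fn=%d)\n",
              id$precision, id$recall, id$f_measure, id$tp, id$fp, id$fn))
  cat("Polarity (macro-averaged), one cell per method x n:\n")
  tab <- x$cells
  tab$macro_p <- round(tab$macro_p, digits)
  tab$macro_r <- round(tab$macro_r, digits)
  tab$macro_f <- round(tab$macro_f, digits)
  tab$micro_p <- round(tab$micro_p, digits)
  tab$micro_r <- round(tab$micro_r, digits)
  tab$micro_f <- round(tab$micro_f, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a sweep report
#' @param report a [run_sweep()] result.
#' @param path output path.
#' @rdname write_sweep
#' @export
write_sweep_tsv <- function(report, path) {
  utils::write.table(report$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
write_sweep_json <- function(report, path) {
  jsonlite::write_json(list(identification = report$identification,
                            cells = report$cells),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
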