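# Span-level scoring of predicted concept annotations against gold
# annotations, and readers/writers for the i2b2-2010 `.con` annotation
# format (1-based lines, 0-based tokens).

#' Precision, recall and F1 from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 is
#' their harmonic mean. Degenerate denominators follow the usual
#' conventions: precision is 0 when nothing was predicted, recall is 0
#' when there is no gold, F1 is 0 when precision + recall is 0.
#'
#' @param tp,fp,fn Nonnegative integer counts.
#' @return Named numeric vector `c(precision, recall, f1)`, each in
#'   `[0, 1]`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be nonnegative")
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- f1_score(p, r)
  c(precision = p, recall = r, f1 = f)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Rates on the same scale (both proportions or
#'   both percentages).
#' @return The F1 score on that scale (0 when both inputs are 0).
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Boundary-detection sensitivity
#'
#' `TP / (TP + FN)`: the fraction of gold concept spans that survive
#' word-boundary detection.
#'
#' @param tp,fn Nonnegative counts with `tp + fn > 0`.
#' @return A proportion in `[0, 1]`.
#' @export
sensitivity <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be nonnegative")
  if (tp + fn == 0) stop("sensitivity undefined: tp + fn == 0")
  tp / (tp + fn)
}

#' Macro-averaged precision, recall and F-score
#'
#' For `N` classes with true-positive counts `TP_i`, inferred-label totals
#' `TI_i` and ground-truth totals `TT_i`:
#' `fP = (1/N) * sum(TP_i / TI_i)`, `fR = (1/N) * sum(TP_i / TT_i)`, and
#' `fF` is the harmonic mean of `fP` and `fR`. A class with no inferred
#' labels contributes 0 to `fP` (and symmetrically for `fR`), with a
#' message noting the degenerate class.
#'
#' @param per_class A data.frame (or list coercible to one) with columns
#'   `tp`, `ti`, `tt`, one row per class.
#' @return Named numeric vector `c(fP, fR, fF)`.
#' @export
macro_average <- function(per_class) {
  per_class <- as.data.frame(per_class)
  n <- nrow(per_class)
  if (n < 1L) stop("macro_average needs at least one class")
  frac <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) message(sprintf("%d class(es) with zero %s contribute 0",
                                  sum(bad), what))
    out <- ifelse(bad, 0, num / den)
    out
  }
  fP <- mean(frac(per_class$tp, per_class$ti, "inferred labels"))
  fR <- mean(frac(per_class$tp, per_class$tt, "ground-truth labels"))
  c(fP = fP, fR = fR, fF = f1_score(fP, fR))
}

# ---- i2b2 .con format -----------------------------------------------------

.con_pattern <- paste0(
  "^c=\"(.*)\" ([0-9]+):([0-9]+) ([0-9]+):([0-9]+)\\|\\|t=\"([a-z]+)\"\\s*$")

#' Read annotations from an i2b2 `.con` file
#'
#' Parses lines of the form
#' `c="<text>" <line>:<tok> <line>:<tok>||t="<category>"` (lines 1-based,
#' tokens 0-based). Blank lines are skipped; a malformed line raises an
#' error naming its line number.
#'
#' @param path Path to a `.con` file.
#' @param doc_id Document identifier attached to every parsed annotation.
#' @return A list of annotations: `list(doc_id, text, line, start, end,
#'   category)`.
#' @export
read_i2b2_con <- function(path, doc_id = "doc") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    m <- regmatches(lines[i], regexec(.con_pattern, lines[i]))[[1]]
    if (length(m) == 0L)
      stop(sprintf("%s: malformed .con line %d: %s", path, i, lines[i]))
    cat_ <- m[7]
    if (!cat_ %in% c("problem", "treatment", "test"))
      stop(sprintf("%s: unknown category '%s' on line %d", path, cat_, i))
    out[[length(out) + 1L]] <- list(
      doc_id = doc_id, text = m[2],
      line = as.integer(m[3]), start = as.integer(m[4]),
      end = as.integer(m[6]), category = cat_)
    if (as.integer(m[3]) != as.integer(m[5]))
      stop(sprintf("%s: span crosses lines on line %d", path, i))
  }
  out
}

#' Write annotations to an i2b2 `.con` file
#'
#' Inverse of [read_i2b2_con()]: `write_i2b2_con(read_i2b2_con(x), x)`
#' reproduces the file modulo whitespace.
#'
#' @param annotations List of annotations with `text`, `line`, `start`,
#'   `end`, `category`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_i2b2_con <- function(annotations, path) {
  lines <- vapply(annotations, function(a) {
    sprintf('c="%s" %d:%d %d:%d||t="%s"', a$text,
            a$line, a$start, a$line, a$end, a$category)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- span evaluation ------------------------------------------------------

.ann_key_df <- function(anns) {
  data.frame(
    doc_id = vapply(anns, function(a) a$doc_id %||% "", ""),
    line = vapply(anns, function(a) as.integer(a$line), 1L),
    start = vapply(anns, function(a) as.integer(a$start), 1L),
    end = vapply(anns, function(a) as.integer(a$end), 1L),
    category = vapply(anns, function(a) a$category, ""),
    stringsAsFactors = FALSE)
}

.span_matches <- function(p, g, mode) {
  same <- p$doc_id == g$doc_id & p$line == g$line & p$category == g$category
  if (mode == "exact") same & p$start == g$start & p$end == g$end
  else same & p$start <= g$end & g$start <= p$end
}

#' Score predicted annotations against gold annotations
#'
#' Matches predictions to gold spans one-to-one, greedily left-to-right: a
#' true positive is a prediction matching an unmatched gold span of the
#' same category, either on the exact token span (`mode = "exact"`) or on
#' any token overlap (`mode = "overlap"`). Unmatched predictions are false
#' positives; unmatched gold spans are false negatives. Reports per-class
#' and overall counts, precision/recall/F1, macro averages and detection
#' sensitivity.
#'
#' @param pred,gold Lists of annotations (`doc_id`, `line`, `start`,
#'   `end`, `category`).
#' @param mode Span-matching protocol: `"exact"` (default, stricter) or
#'   `"overlap"`.
#' @return A `clin_metrics` list: `per_class` data.frame (rows problem /
#'   treatment / test with `tp`, `fp`, `fn`, `ti`, `tt`, `precision`,
#'   `recall`, `f1`), `overall` named vector (`tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `sensitivity`), `macro` named vector
#'   (`fP`, `fR`, `fF`), and `mode`.
#' @export
evaluate_annotations <- function(pred, gold, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  pd <- .ann_key_df(pred)
  gd <- .ann_key_df(gold)
  gd$matched <- FALSE
  tp_class <- c(problem = 0L, treatment = 0L, test = 0L)
  fp_class <- c(problem = 0L, treatment = 0L, test = 0L)
  if (nrow(pd) > 0) {
    for (i in seq_len(nrow(pd))) {
      hit <- which(!gd$matched & .span_matches(pd[i, ], gd, mode))
      if (length(hit) > 0L) {
        gd$matched[hit[1L]] <- TRUE
        tp_class[pd$category[i]] <- tp_class[pd$category[i]] + 1L
      } else {
        fp_class[pd$category[i]] <- fp_class[pd$category[i]] + 1L
      }
    }
  }
  fn_class <- vapply(names(tp_class), function(cl)
    sum(!gd$matched & gd$category == cl), integer(1))
  per_class <- data.frame(
    category = names(tp_class), tp = as.integer(tp_class),
    fp = as.integer(fp_class), fn = as.integer(fn_class),
    stringsAsFactors = FALSE)
  per_class$ti <- per_class$tp + per_class$fp
  per_class$tt <- per_class$tp + per_class$fn
  prf <- t(mapply(precision_recall_f1, per_class$tp, per_class$fp,
                  per_class$fn))
  per_class <- cbind(per_class, prf)
  tp <- sum(per_class$tp); fp <- sum(per_class$fp); fn <- sum(per_class$fn)
  overall <- c(tp = tp, fp = fp, fn = fn, precision_recall_f1(tp, fp, fn),
               sensitivity = if (tp + fn > 0) sensitivity(tp, fn) else NA_real_)
  macro <- suppressMessages(
    macro_average(per_class[, c("tp", "ti", "tt")]))
  structure(list(per_class = per_class, overall = overall, macro = macro,
                 mode = mode),
            class = "clin_metrics")
}

#' @export
print.clin_metrics <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", round(100 * v, 2))
  cat(sprintf("Span evaluation (%s matching)\n", x$mode))
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("  %-9s TP=%-4d FP=%-4d FN=%-4d P=%s R=%s F1=%s\n",
                r$category, r$tp, r$fp, r$fn, pct(r$precision),
                pct(r$recall), pct(r$f1)))
  }
  o <- x$overall
  cat(sprintf("  overall   TP=%-4d FP=%-4d FN=%-4d P=%s R=%s F1=%s\n",
              o["tp"], o["fp"], o["fn"], pct(o["precision"]),
              pct(o["recall"]), pct(o["f1"])))
  cat(sprintf("  macro     fP=%s fR=%s fF=%s\n",
              pct(x$macro["fP"]), pct(x$macro["fR"]), pct(x$macro["fF"])))
  if (!is.na(o["sensitivity"]))
    cat(sprintf("  sensitivity %s\n", pct(o["sensitivity"])))
  invisible(x)
}
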