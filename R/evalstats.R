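#' Confusion matrix of detector calls against gold standard
#'
#' Tallies true/false positives and negatives for one item over the
#' documents present in both the call set and the gold annotations. Calls
#' for documents without gold annotation are excluded from the tally but
#' counted (attribute and field `extra_calls`); gold rows without a call
#' are an error, since every annotated document should have been classified.
#'
#' @param calls an `rob_calls` data frame ([classify_corpus()]).
#' @param gold an `rob_gold` data frame ([load_gold()]).
#' @param item one of `"randomization"`, `"blinding"`, `"samplesize"`.
#' @return Object of class `rob_confusion`: list with integer counts `tp`,
#'   `fp`, `tn`, `fn`, their total `n`, plus `item` and `extra_calls`.
#' @export
confusion_matrix <- function(calls, gold, item) {
  check_item(item)
  cc <- calls[calls$item == item, , drop = FALSE]
  common <- intersect(cc$doc_id, gold$doc_id)
  if (length(common) == 0L) {
    abort("no overlap between call and gold doc_ids for item ", item)
  }
  no_call <- setdiff(gold$doc_id, cc$doc_id)
  if (length(no_call)) {
    abort("gold documents without a call for ", item, ": ",
          paste(utils::head(no_call, 5), collapse = ", "))
  }
  pred <- cc$call[match(common, cc$doc_id)]
  truth <- gold[[item]][match(common, gold$doc_id)]
  structure(list(item = item,
                 tp = sum(pred & truth), fp = sum(pred & !truth),
                 tn = sum(!pred & !truth), fn = sum(!pred & truth),
                 n = length(common),
                 extra_calls = length(setdiff(cc$doc_id, gold$doc_id))),
            class = "rob_confusion")
}

#' @export
print.rob_confusion <- function(x, ...) {
  cat(sprintf("<rob_confusion> %s (n=%d): tp=%d fp=%d tn=%d fn=%d\n",
              x$item, x$n, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Exact (Clopper\enc{–}{-}Pearson) binomial confidence interval
#'
#' The exact interval for a binomial proportion, obtained from Beta
#' quantiles: with `a = 1 - level`,
#' `low = qbeta(a/2, k, n - k + 1)` (0 when `k = 0`) and
#' `high = qbeta(1 - a/2, k + 1, n - k)` (1 when `k = n`). This is the
#' interval produced by inverting the binomial tail probabilities, and is
#' conservative: realised coverage is at least the nominal level.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level in (0, 1); default 0.95.
#' @return Object of class `exact_ci`: list with `k`, `n`, `level`,
#'   `estimate` (`k/n`), `low`, `high`.
#' @examples
#' clopper_pearson(0, 10)   # high = 1 - (0.025)^(1/10)
#' clopper_pearson(5, 10)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    abort("clopper_pearson() needs integers 0 <= k <= n with n >= 1")
  }
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1)")
  }
  a <- 1 - level
  low <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  structure(list(k = as.integer(k), n = as.integer(n), level = level,
                 estimate = k / n, low = low, high = high),
            class = "exact_ci")
}

#' @export
print.exact_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.4f, %.0f%% exact CI [%.4f, %.4f]\n",
              x$k, x$n, x$estimate, 100 * x$level, x$low, x$high))
  invisible(x)
}

#' Diagnostic accuracy of the detector against the gold standard
#'
#' Sensitivity (`tp / (tp + fn)`: gold positives the tool finds),
#' specificity (`tn / (tn + fp)`: gold negatives the tool clears) and
#' accuracy (`(tp + tn) / n`: documents labelled correctly), each with an
#' exact binomial confidence interval, plus the tool-called and gold
#' prevalences. A zero denominator (no gold positives, or no gold
#' negatives) leaves the corresponding metric and interval `NA` with its
#' `*_defined` flag `FALSE` — it is never silently coerced to 0 or 1.
#' When all terms are defined the identity
#' `accuracy = prevalence_gold * sensitivity +
#' (1 - prevalence_gold) * specificity` holds exactly.
#'
#' @param cm an `rob_confusion` object (or list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @param level confidence level for the intervals; default 0.95.
#' @return Object of class `rob_metrics`: list with `item`, `cm`, `n`,
#'   `prevalence_tool`, `prevalence_gold`, and for each of `sensitivity`,
#'   `specificity`, `accuracy` the point estimate, an `exact_ci`, and a
#'   `*_defined` flag.
#' @export
diagnostic_metrics <- function(cm, level = 0.95) {
  counts <- c(cm$tp, cm$fp, cm$tn, cm$fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("confusion counts must be non-negative")
  }
  n <- sum(counts)
  if (n == 0) abort("empty confusion matrix (n = 0)")
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  sens_def <- pos > 0
  spec_def <- neg > 0
  structure(list(
    item = cm$item %||% NA_character_,
    cm = cm, n = n,
    prevalence_tool = (cm$tp + cm$fp) / n,
    prevalence_gold = pos / n,
    sensitivity = if (sens_def) cm$tp / pos else NA_real_,
    sensitivity_ci = if (sens_def) clopper_pearson(cm$tp, pos, level) else NULL,
    sensitivity_defined = sens_def,
    specificity = if (spec_def) cm$tn / neg else NA_real_,
    specificity_ci = if (spec_def) clopper_pearson(cm$tn, neg, level) else NULL,
    specificity_defined = spec_def,
    accuracy = (cm$tp + cm$tn) / n,
    accuracy_ci = clopper_pearson(cm$tp + cm$tn, n, level),
    level = level), class = "rob_metrics")
}

#' @export
print.rob_metrics <- function(x, ...) {
  fmt <- function(v, ci, def) {
    if (!def) return("undefined (zero denominator)")
    sprintf("%.2f [%.2f, %.2f]", v, ci$low, ci$high)
  }
  cat(sprintf("<rob_metrics> %s (n=%d)\n", x$item, x$n))
  cat("  sensitivity:", fmt(x$sensitivity, x$sensitivity_ci,
                            x$sensitivity_defined), "\n")
  cat("  specificity:", fmt(x$specificity, x$specificity_ci,
                            x$specificity_defined), "\n")
  cat("  accuracy:   ", fmt(x$accuracy, x$accuracy_ci, TRUE), "\n")
  cat(sprintf("  prevalence: tool %.0f%%, gold %.0f%%\n",
              100 * x$prevalence_tool, 100 * x$prevalence_gold))
  invisible(x)
}

#' Evaluate a call set against gold annotations, one row per item
#'
#' Convenience wrapper producing the summary-table layout used for
#' published performance tables: per item, tool and gold prevalence,
#' sensitivity, specificity and accuracy with exact confidence bounds.
#'
#' @inheritParams confusion_matrix
#' @param level confidence level; default 0.95.
#' @return Data frame with one row per item and columns `item`, `n`, `tp`,
#'   `fp`, `tn`, `fn`, `prevalence_tool`, `prevalence_gold`,
#'   `sensitivity`, `sensitivity_low`, `sensitivity_high`, `specificity`,
#'   `specificity_low`, `specificity_high`, `accuracy`, `accuracy_low`,
#'   `accuracy_high`.
#' @export
evaluate_calls <- function(calls, gold, level = 0.95) {
  rows <- lapply(ROB_ITEMS, function(item) {
    m <- diagnostic_metrics(confusion_matrix(calls, gold, item), level)
    data.frame(
      item = item, n = m$n, tp = m$cm$tp, fp = m$cm$fp, tn = m$cm$tn,
      fn = m$cm$fn,
      prevalence_tool = m$prevalence_tool,
      prevalence_gold = m$prevalence_gold,
      sensitivity = m$sensitivity,
      sensitivity_low = if (m$sensitivity_defined) m$sensitivity_ci$low else NA_real_,
      sensitivity_high = if (m$sensitivity_defined) m$sensitivity_ci$high else NA_real_,
      specificity = m$specificity,
      specificity_low = if (m$specificity_defined) m$specificity_ci$low else NA_real_,
      specificity_high = if (m$specificity_defined) m$specificity_ci$high else NA_real_,
      accuracy = m$accuracy,
      accuracy_low = m$accuracy_ci$low,
      accuracy_high = m$accuracy_ci$high,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reconstruct a confusion matrix from published summary statistics
#'
#' Performance tables usually print corpus size, gold prevalence,
#' sensitivity and specificity but not the underlying counts. This inverts
#' the summary: `tp = round(n * prev * sens)`,
#' `fn = round(n * prev) - tp`, `tn = round(n * (1 - prev) * spec)`,
#' `fp = n - tp - fn - tn`. It also returns the implied accuracy
#' `prev * sens + (1 - prev) * spec` and the implied tool call rate
#' `prev * sens + (1 - prev) * (1 - spec)`, which can be checked against a
#' table's printed accuracy and call-rate columns. Because the published
#' inputs are themselves rounded, recovered metrics carry an uncertainty
#' of about one unit in the last printed digit.
#'
#' @param n corpus size (integer, `>= 1`).
#' @param prevalence_gold gold-standard prevalence in \[0, 1\].
#' @param sensitivity,specificity published proportions in \[0, 1\].
#' @return List of class `rob_reconstruction`: `cm` (an `rob_confusion`),
#'   `implied_accuracy`, `implied_call_rate`.
#' @examples
#' r <- reconstruct_counts(918, 0.60, 1.00, 0.67)
#' round_half_up(100 * r$implied_accuracy)   # 87
#' round_half_up(100 * r$implied_call_rate)  # 73
#' @export
reconstruct_counts <- function(n, prevalence_gold, sensitivity, specificity) {
  p <- c(prevalence_gold, sensitivity, specificity)
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("prevalence, sensitivity and specificity must lie in [0, 1]")
  }
  tp <- round(n * prevalence_gold * sensitivity)
  fn <- round(n * prevalence_gold) - tp
  tn <- round(n * (1 - prevalence_gold) * specificity)
  fp <- n - tp - fn - tn
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) {
    abort("inconsistent summary statistics: implied negative count(s) ",
          paste(sprintf("%s=%d", names(counts)[counts < 0],
                        counts[counts < 0]), collapse = ", "))
  }
  cm <- structure(list(item = NA_character_, tp = tp, fp = fp, tn = tn,
                       fn = fn, n = n, extra_calls = 0L),
                  class = "rob_confusion")
  structure(list(
    cm = cm,
    implied_accuracy = prevalence_gold * sensitivity +
      (1 - prevalence_gold) * specificity,
    implied_call_rate = prevalence_gold * sensitivity +
      (1 - prevalence_gold) * (1 - specificity)),
    class = "rob_reconstruction")
}
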