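calls_from <- function(doc_ids, item, pred) {
  data.frame(doc_id = doc_ids, item = item, call = pred,
             n_matches = as.integer(pred), first_snippet = "")
}

test_that("confusion matrix: agreement, degenerate classifier, extra calls", {
  ids <- sprintf("d%02d", 1:10)
  gold <- make_gold(ids, rand = c(rep(TRUE, 4), rep(FALSE, 6)))
  # calls identical to gold
  cm <- confusion_matrix(calls_from(ids, "randomization", gold$randomization),
                         gold, "randomization")
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 4, fp = 0, tn = 6, fn = 0))
  # everything called positive, 3 of 10 truly positive
  gold3 <- make_gold(ids, rand = c(rep(TRUE, 3), rep(FALSE, 7)))
  cm2 <- confusion_matrix(calls_from(ids, "randomization", rep(TRUE, 10)),
                          gold3, "randomization")
  expect_equal(unlist(cm2[c("tp", "fp", "tn", "fn")]),
               c(tp = 3, fp = 7, tn = 0, fn = 0))
  # calls without gold are excluded but counted
  extra <- calls_from(c(ids, "extra1"), "randomization",
                      c(gold$randomization, TRUE))
  cm3 <- confusion_matrix(extra, gold, "randomization")
  expect_equal(cm3$n, 10)
  expect_equal(cm3$extra_calls, 1)
  # no overlap at all is fatal
  expect_error(confusion_matrix(calls_from("zz", "randomization", TRUE),
                                gold, "randomization"), "no overlap")
})

test_that("confusion matrix equals a per-document tally loop on random instances", {
  set.seed(61)
  for (rep in 1:25) {
    n <- 50
    ids <- sprintf("r%03d", 1:n)
    truth <- runif(n) < runif(1)
    pred <- ifelse(runif(n) < 0.8, truth, !truth)
    gold <- make_gold(ids, rand = truth)
    cm <- confusion_matrix(calls_from(ids, "randomization", pred), gold,
                           "randomization")
    want <- brute_confusion(pred, truth)
    expect_equal(cm[c("tp", "fp", "tn", "fn")], want)
  }
})

test_that("metrics reproduce a published summary row reconstructed from counts", {
  rec <- reconstruct_counts(918, 0.60, 1.00, 0.67)
  m <- diagnostic_metrics(rec$cm)
  expect_equal(m$sensitivity, 1.00)
  expect_equal(round_half_up(m$specificity, 2), 0.67)
  expect_equal(round_half_up(100 * m$accuracy), 87)
  expect_equal(round_half_up(100 * m$prevalence_tool), 73)
})

test_that("a perfect classifier scores 1.0 on every metric", {
  m <- diagnostic_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
})

test_that("zero denominators are flagged undefined, never coerced", {
  m <- diagnostic_metrics(list(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_false(m$sensitivity_defined)
  expect_true(is.na(m$sensitivity))
  expect_null(m$sensitivity_ci)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  expect_error(diagnostic_metrics(list(tp = 0, fn = 0, tn = 0, fp = 0)),
               "empty")
})

test_that("the accuracy identity holds exactly whenever all terms are defined", {
  set.seed(71)
  for (rep in 1:100) {
    counts <- as.list(rmultinom(1, sample(5:200, 1), runif(4, 0.05, 1))[, 1])
    names(counts) <- c("tp", "fp", "tn", "fn")
    if ((counts$tp + counts$fn) == 0 || (counts$tn + counts$fp) == 0) next
    m <- diagnostic_metrics(counts)
    expect_equal(m$accuracy,
                 m$prevalence_gold * m$sensitivity +
                   (1 - m$prevalence_gold) * m$specificity)
  }
})

test_that("exact interval closed forms hold at k = 0 and k = n", {
  ci0 <- clopper_pearson(0, 10)
  expect_equal(ci0$low, 0)
  expect_equal(ci0$high, 1 - 0.025^(1 / 10), tolerance = 1e-12)
  cin <- clopper_pearson(10, 10)
  expect_equal(cin$high, 1)
  expect_equal(cin$low, 0.025^(1 / 10), tolerance = 1e-12)
})

test_that("exact intervals agree with binom.test and the tail-bisection oracle", {
  for (k in c(0, 1, 5, 9, 10)) {
    ci <- clopper_pearson(k, 10)
    bt <- binom.test(k, 10)$conf.int
    expect_equal(c(ci$low, ci$high), as.numeric(bt), tolerance = 1e-9)
  }
  set.seed(81)
  ns <- sample(1:50, 15, replace = TRUE)
  ks <- vapply(ns, function(n) sample(0:n, 1), 0L)
  for (level in c(0.90, 0.95, 0.99)) {
    want <- brute_cp(ks, ns, level)
    for (i in seq_along(ns)) {
      ci <- clopper_pearson(ks[i], ns[i], level)
      expect_equal(ci$low, want$low[i], tolerance = 1e-9)
      expect_equal(ci$high, want$high[i], tolerance = 1e-9)
    }
  }
})

test_that("interval ordering and width behaviour", {
  # 0 <= low <= k/n <= high <= 1 across the grid
  for (n in c(1, 7, 30)) {
    for (k in 0:n) {
      ci <- clopper_pearson(k, n)
      expect_true(ci$low >= 0 && ci$low <= k / n)
      expect_true(ci$high <= 1 && ci$high >= k / n)
    }
  }
  # width is non-increasing in n at a fixed k/n ratio
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    ci <- clopper_pearson(n * 0.3, n)
    ci$high - ci$low
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("clopper_pearson rejects domain violations", {
  expect_error(clopper_pearson(5, 4), "0 <= k <= n")
  expect_error(clopper_pearson(-1, 4), "0 <= k <= n")
  expect_error(clopper_pearson(1, 4, level = 1), "level")
})

test_that("reconstruction inverts published summaries within rounding", {
  # boundary identity: prevalence 1 makes accuracy the sensitivity
  rec <- reconstruct_counts(50, 1, 0.8, 0.3)
  expect_equal(rec$implied_accuracy, 0.8)
  expect_error(reconstruct_counts(10, 0.05, 10, 0.5), "\\[0, 1\\]")
  # metrics recovered from reconstructed counts match inputs to +/- 1/n
  set.seed(91)
  for (rep in 1:50) {
    n <- sample(20:1000, 1)
    prev <- runif(1, 0.05, 0.95)
    sens <- runif(1)
    spec <- runif(1)
    rec <- reconstruct_counts(n, prev, sens, spec)
    m <- diagnostic_metrics(rec$cm)
    pos <- rec$cm$tp + rec$cm$fn
    neg <- rec$cm$tn + rec$cm$fp
    expect_lt(abs(m$sensitivity - sens), 1 / pos + 1e-9)
    expect_lt(abs(m$specificity - spec), 1 / neg + 1e-9)
    expect_equal(rec$cm$tp + rec$cm$fp + rec$cm$tn + rec$cm$fn, n)
  }
})

test_that("evaluate_calls produces one fully populated row per item", {
  gen <- generate_corpus(synth_config(n_docs = 40, seed = 5))
  calls <- classify_corpus(gen$corpus)
  report <- evaluate_calls(calls, gen$gold)
  expect_equal(report$item, ITEMS)
  expect_true(all(report$n == 40))
  expect_true(all(report$accuracy >= report$accuracy_low &
                    report$accuracy <= report$accuracy_high))
})
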