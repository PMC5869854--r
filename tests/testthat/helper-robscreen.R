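# Shared fixtures and independent oracles for the robscreen test suite.

ITEMS <- c("randomization", "blinding", "samplesize")

# Write a corpus directory + metadata CSV from a named character vector of
# texts; returns the paths. Journals/dates default to something valid.
make_corpus_dir <- function(texts, journals = NULL, dates = NULL,
                            dir = withr::local_tempdir(.local_envir = parent.frame())) {
  text_dir <- file.path(dir, "texts")
  dir.create(text_dir, showWarnings = FALSE)
  for (id in names(texts)) {
    writeLines(texts[[id]], file.path(text_dir, paste0(id, ".txt")))
  }
  meta <- data.frame(
    doc_id = names(texts),
    journal = journals %||% rep("journal a", length(texts)),
    record_date = dates %||% rep("2016-01-01", length(texts)))
  meta_path <- file.path(dir, "metadata.csv")
  write.csv(meta, meta_path, row.names = FALSE)
  list(text_dir = text_dir, metadata = meta_path, dir = dir)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Word soup for randomly generated texts: single words plus whole trigger
# and confounder phrases as units, so include and exclude patterns fire
# often and overlap in varied ways.
ORACLE_VOCAB <- c(
  "randomly", "allocated", "assigned", "divided", "random", "hexamer",
  "primers", "allocation", "number", "table", "generator", "effects",
  "blinded", "blind", "fashion", "manner", "observer", "assessor",
  "masked", "to", "the", "group", "treatment", "unaware", "of",
  "blindness", "double", "placebo", "trial", "power", "analysis",
  "calculation", "sample", "size", "was", "calculated", "a", "priori",
  "high", "field", "supply", "spectral", "animals", "were", "rats",
  "in", "and", "study", "groups", "selected", "section", "clinical",
  # phrase units
  "randomly allocated", "randomly assigned to groups", "random allocation",
  "random hexamer primers", "random effects", "randomly selected fields",
  "randomly distributed across", "randomly distributed between",
  "blinded observer", "in a blinded", "blinded clinical trial",
  "double blind placebo", "observer-blind", "masked to the treatment",
  "blind ended", "power analysis", "power calculation", "spectral power",
  "sample size was calculated", "a priori power", "high power fields",
  "power supply", "statistical power of 0.8")

random_text <- function(n_words = 30, vocab = ORACLE_VOCAB) {
  paste(sample(vocab, n_words, replace = TRUE), collapse = " ")
}

# Brute-force detector: enumerate every include match, every exclude match,
# subtract overlap with explicit nested loops, aggregate.
brute_detect <- function(text, patterns, item) {
  norm <- normalize_text(text)$text
  inc <- list()
  for (id in names(patterns[[item]]$include)) {
    m <- gregexpr(patterns[[item]]$include[[id]], norm, perl = TRUE)[[1]]
    if (m[1] != -1) {
      for (j in seq_along(m)) {
        inc[[length(inc) + 1]] <- list(id = id, start = m[j],
                                       end = m[j] + attr(m, "match.length")[j] - 1)
      }
    }
  }
  exc <- list()
  for (id in names(patterns[[item]]$exclude)) {
    m <- gregexpr(patterns[[item]]$exclude[[id]], norm, perl = TRUE)[[1]]
    if (m[1] != -1) {
      for (j in seq_along(m)) {
        exc[[length(exc) + 1]] <- c(m[j], m[j] + attr(m, "match.length")[j] - 1)
      }
    }
  }
  surviving <- Filter(function(hit) {
    for (e in exc) {
      if (hit$start <= e[2] && e[1] <= hit$end) return(FALSE)
    }
    TRUE
  }, inc)
  ord <- order(vapply(surviving, `[[`, 0, "start"),
               vapply(surviving, `[[`, 0, "end"))
  list(call = length(surviving) > 0, matches = surviving[ord])
}

# Clopper-Pearson by bisection on the exact binomial tails, vectorised over
# (k, n) pairs: low solves P(X >= k | p) = alpha/2 (0 when k = 0), high
# solves P(X <= k | p) = alpha/2 (1 when k = n).
brute_cp <- function(k, n, level, iters = 60) {
  a <- 1 - level
  bisect <- function(f) {
    lo <- rep(0, length(k))
    hi <- rep(1, length(k))
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      up <- f(mid)
      lo <- ifelse(up, lo, mid)
      hi <- ifelse(up, mid, hi)
    }
    (lo + hi) / 2
  }
  low <- bisect(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) >= a / 2)
  high <- bisect(function(p) pbinom(k, n, p) < a / 2)
  low[k == 0] <- 0
  high[k == n] <- 1
  list(low = low, high = high)
}

# Per-document tally loop for the confusion matrix.
brute_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1
    else if (pred[i] && !truth[i]) fp <- fp + 1
    else if (!pred[i] && !truth[i]) tn <- tn + 1
    else fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# A gold table matching a calls data frame, with chosen truth values.
make_gold <- function(doc_ids, rand = FALSE, blind = FALSE, ss = FALSE) {
  structure(data.frame(doc_id = doc_ids,
                       randomization = rep_len(rand, length(doc_ids)),
                       blinding = rep_len(blind, length(doc_ids)),
                       samplesize = rep_len(ss, length(doc_ids))),
            class = c("rob_gold", "data.frame"))
}
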