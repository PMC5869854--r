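# ---- phrase banks -----------------------------------------------------------
# Positive phrasings at three paraphrase-hardness levels per item, plus
# confounder phrases (item keywords in a non-relevant sense) for negatives.
# Level 0 plants verbatim instantiations of the shipped seed lexicon;
# level 1 plants paraphrases sharing its keywords (most, not all, still
# match); level 2 plants paraphrases that avoid the lexicon keywords
# entirely. Filler sentences are methods-section boilerplate curated to be
# free of all lexicon keywords.

SYNTH_PHRASES <- list(
  randomization = list(
    h0 = c(
      "animals were randomly allocated to treatment groups",
      "rats were randomly assigned to experimental groups",
      "mice were randomised into two groups",
      "group membership followed a random allocation procedure",
      "the randomization schedule was generated before surgery",
      "a random number table was used for group assignment",
      "animals were randomly divided into four groups",
      "subjects were randomly assigned to either vehicle or drug",
      "the randomisation sequence was concealed until surgery",
      "animals were randomized to the groups using a random number generator"),
    h1 = c(
      "each animal was randomly assigned by cage to one of the study arms",
      "the animals were randomised into surgery and sham groups",
      "allocation to groups was performed using a random number generator",
      "a computer generated randomization list determined group membership",
      "animals were allocated at random to receive either treatment",
      "the experimenter randomly divided the cohort into equal groups",
      "assignment was randomized to balance the groups for body weight",
      "surgeons used a random number table to assign animals",
      "litters were randomly distributed between the two conditions",
      "the random allocation of subjects was stratified by weight"),
    h2 = c(
      "animals were assigned to groups by coin toss",
      "group membership was decided by drawing lots",
      "cage cards were shuffled to determine treatment order",
      "assignment used sealed opaque envelopes opened at surgery",
      "a lottery procedure determined which animals received treatment",
      "treatment order was decided by rolling a die before each surgery"),
    confounder = c(
      "cdna was synthesized using random hexamer primers",
      "random primers were used for reverse transcription",
      "randomly selected fields were photographed for analysis",
      "cells appeared randomly distributed across the culture surface",
      "a random effects model was used for the meta analysis",
      "lesions were randomly distributed throughout the striatum")),
  blinding = list(
    h0 = c(
      "outcome assessment was performed in a blinded fashion",
      "histology was scored by a blinded observer",
      "neurological scores were obtained in a blinded manner",
      "an investigator blinded to treatment performed the analysis",
      "the assessor was masked to the treatment condition",
      "evaluators were unaware of the group allocation",
      "lesion volumes were measured by a blinded examiner",
      "outcomes were assessed observer-blind",
      "sections were analysed in a blinded assessment by one rater",
      "the examiner was masked to group identity during scoring"),
    h1 = c(
      "staining was quantified by an observer blinded to the condition",
      "a second investigator, blinded to allocation, repeated the measurements",
      "behavioural tests were video recorded and rated in a blinded manner",
      "personnel performing infarct measurement were masked to treatment",
      "the rater remained unaware of the treatment assignment throughout",
      "images were coded and analysed in a blinded fashion by two raters",
      "functional outcome was determined assessor-blind at day seven",
      "tissue analysis was undertaken by a blinded investigator",
      "slides were examined in a blinded evaluation by the pathologist",
      "scoring was done by an examiner masked to the group of each animal"),
    h2 = c(
      "the rater did not know which treatment each animal had received",
      "group identity was concealed from the person scoring outcomes",
      "samples were coded so the analyst could not tell the groups apart",
      "treatment labels were hidden during all outcome measurements",
      "the person assessing outcomes had no knowledge of treatment condition",
      "slides were relabelled with neutral codes before scoring"),
    confounder = c(
      "a blind ended catheter was inserted into the carotid artery",
      "as reported in a blinded clinical trial of thrombolysis",
      "patients in the double blind placebo controlled study improved",
      "diabetic retinopathy can progress to blindness",
      "the double blind trial design is standard in clinical research",
      "a blinded clinical study protocol was adapted for this work")),
  samplesize = list(
    h0 = c(
      "a sample size calculation was performed before the study",
      "sample size was calculated to detect a 20% reduction in volume",
      "we performed a power calculation to determine group sizes",
      "group sizes were determined by a priori power analysis",
      "a power analysis indicated eight animals per group",
      "sample size estimation assumed a standard deviation of 15%",
      "the study was designed to achieve a statistical power of 0.80",
      "sample size was determined using pilot data",
      "to detect a difference of 25% between groups with 90% power",
      "sample size was estimated assuming an effect size of 1.2"),
    h1 = c(
      "the number of animals per group was fixed by a power calculation",
      "an a priori power analysis determined the group size",
      "sample size estimation was based on previous studies in our laboratory",
      "group size was chosen to provide 80% power to detect the expected effect",
      "we aimed to detect a difference of one point with 90% power",
      "a power analysis based on pilot experiments suggested ten animals",
      "group sizes were derived from a sample size calculation with alpha 0.05",
      "sample size was calculated a priori using published variance estimates",
      "assuming a statistical power of 0.9 we required twelve animals",
      "power calculation details are given in the supplementary methods"),
    h2 = c(
      "the number of animals needed was computed from expected variance",
      "we estimated how many animals per group were required before starting",
      "group n was justified by a formal calculation of detectable effect",
      "the required number of subjects was determined statistically in advance",
      "animal numbers were fixed in advance by a formal design calculation",
      "an advance calculation showed ten animals per group would suffice"),
    confounder = c(
      "vessels were counted in five high power fields per section",
      "the power supply was set to 12 volts during electrophoresis",
      "spectral power analysis of eeg recordings was performed",
      "high powered fields were examined at 400x magnification",
      "spectral power in the delta band increased after occlusion",
      "laser settings were kept constant across imaging sessions")))

SYNTH_FILLER <- c(
  "adult male sprague dawley rats were obtained from the institutional colony",
  "focal cerebral ischaemia was induced by occlusion of the middle cerebral artery",
  "body temperature was maintained at 37 degrees with a heating pad",
  "anaesthesia was induced with isoflurane in oxygen and nitrous oxide",
  "infarct volume was quantified on ttc stained coronal sections",
  "neurological deficits were scored daily for seven days after surgery",
  "animals had free access to food and water throughout the experiment",
  "cerebral blood flow was monitored by laser doppler flowmetry",
  "data are presented as mean and standard deviation",
  "statistical analysis was performed using analysis of variance",
  "the suture was withdrawn after ninety minutes to allow reperfusion",
  "brains were removed and sectioned at two millimetre intervals")

#' Phrase banks used by the synthetic corpus generator
#'
#' Returns the planted-phrase vocabulary: for each item, positive phrasings
#' at hardness levels 0 (verbatim seed-lexicon phrases), 1 (paraphrases
#' sharing lexicon keywords) and 2 (paraphrases avoiding them), plus
#' confounder phrases, and the keyword-free filler sentences.
#'
#' @return Nested list: `$<item>$h0/h1/h2/confounder` character vectors and
#'   `$filler`.
#' @export
synth_phrases <- function() {
  c(SYNTH_PHRASES, list(filler = SYNTH_FILLER))
}

#' Synthetic corpus configuration
#'
#' Study conditions for the deterministic corpus generator. The defaults
#' are the shipped benchmark configuration: 200 documents, 50% gold
#' prevalence per item, paraphrase hardness 1, a confounder phrase in 30%
#' of negative documents, 8 journals with skewed sizes (so that both
#' "five or more manuscripts" and smaller journal groups exist), record
#' dates uniform over the two years to 2016-10-04, seed 20161004.
#'
#' Positive counts are exact by assignment — each item gets
#' `round(n_docs * prevalence)` gold positives, chosen by seeded sampling
#' — rather than Bernoulli draws, so prevalence targets are exactly
#' testable at small n.
#'
#' @param n_docs number of documents (`>= 1`).
#' @param prevalence named proportions in \[0, 1\] per item (single value
#'   recycled to all three).
#' @param hardness paraphrase hardness: 0, 1 or 2.
#' @param confounder_rate probability a negative document carries a
#'   confounder phrase for that item.
#' @param n_journals number of journals (`>= 1`).
#' @param date_range length-2 `Date` (or `YYYY-MM-DD`) vector.
#' @param seed integer seed driving the single pseudo-random stream.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 200,
                         prevalence = 0.5,
                         hardness = 1,
                         confounder_rate = 0.3,
                         n_journals = 8,
                         date_range = c("2014-10-04", "2016-10-04"),
                         seed = 20161004) {
  if (n_docs < 1 || n_docs != round(n_docs)) {
    abort("`n_docs` must be a positive integer")
  }
  if (length(prevalence) == 1L) {
    prevalence <- stats::setNames(rep(prevalence, 3), ROB_ITEMS)
  }
  if (!all(ROB_ITEMS %in% names(prevalence))) {
    abort("`prevalence` must be named for each of: ",
          paste(ROB_ITEMS, collapse = ", "))
  }
  prevalence <- prevalence[ROB_ITEMS]
  if (any(prevalence < 0) || any(prevalence > 1)) {
    abort("prevalence must lie in [0, 1]")
  }
  if (!hardness %in% 0:2) abort("`hardness` must be 0, 1 or 2")
  if (confounder_rate < 0 || confounder_rate > 1) {
    abort("`confounder_rate` must lie in [0, 1]")
  }
  if (n_journals < 1) abort("`n_journals` must be >= 1")
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || anyNA(date_range) ||
      date_range[1L] > date_range[2L]) {
    abort("`date_range` must be two valid dates, start <= end")
  }
  structure(list(n_docs = as.integer(n_docs), prevalence = prevalence,
                 hardness = as.integer(hardness),
                 confounder_rate = confounder_rate,
                 n_journals = as.integer(n_journals),
                 date_range = date_range, seed = as.integer(seed)),
            class = "synth_config")
}

# Skewed deterministic journal sizes: geometric shares, with the last
# journal forced small so a below-threshold group always exists.
journal_sizes <- function(n, J) {
  if (J == 1L) return(n)
  share <- 0.5^(seq_len(J) - 1)
  share <- share / sum(share)
  cnt <- floor(share * n)
  rem <- n - sum(cnt)
  if (rem > 0) cnt[seq_len(rem)] <- cnt[seq_len(rem)] + 1L
  if (n >= 8L) {
    target_small <- 3L
    if (cnt[J] != target_small) {
      cnt[1L] <- cnt[1L] + (cnt[J] - target_small)
      cnt[J] <- target_small
    }
  }
  as.integer(cnt)
}

with_stream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic methods-section corpus with known gold labels
#'
#' Assembles `n_docs` documents of templated methods prose. A document
#' gold-positive for an item carries at least one phrase from that item's
#' positive bank at the configured hardness; a gold-negative document
#' carries none, but with probability `confounder_rate` carries a
#' confounder phrase (e.g. "random hexamer primers"). Journals follow a
#' skewed deterministic allocation; record dates are uniform over
#' `date_range`. The same configuration and seed always produce
#' byte-identical output.
#'
#' @param config a [synth_config()].
#' @return List of class `synth_corpus`: `corpus` (an `rob_corpus` data
#'   frame), `gold` (an `rob_gold` data frame), `planted` (data frame
#'   `doc_id,item,role,phrase` recording every inserted phrase), and
#'   `config`.
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must come from synth_config()")
  }
  n <- config$n_docs
  ids <- sprintf("synth%04d", seq_len(n))
  bank <- SYNTH_PHRASES
  hkey <- paste0("h", config$hardness)

  with_stream(config$seed, {
    gold <- data.frame(doc_id = ids, stringsAsFactors = FALSE)
    for (item in ROB_ITEMS) {
      k <- round(n * config$prevalence[[item]])
      pos <- rep(FALSE, n)
      if (k > 0) pos[sample.int(n, k)] <- TRUE
      gold[[item]] <- pos
    }
    journals <- rep(sprintf("journal of synthetic stroke research %02d",
                            seq_len(config$n_journals)),
                    journal_sizes(n, config$n_journals))[seq_len(n)]
    span <- as.integer(config$date_range[2L] - config$date_range[1L])
    dates <- config$date_range[1L] +
      (if (span > 0) sample.int(span + 1L, n, replace = TRUE) - 1L else 0L)

    planted <- vector("list", n)
    texts <- character(n)
    for (i in seq_len(n)) {
      sentences <- sample(SYNTH_FILLER, 6L)
      extra <- character(0)
      rec <- list()
      for (item in ROB_ITEMS) {
        if (gold[[item]][i]) {
          ph <- sample(bank[[item]][[hkey]], 1L)
          extra <- c(extra, ph)
          rec[[length(rec) + 1L]] <-
            data.frame(doc_id = ids[i], item = item, role = "positive",
                       phrase = ph, stringsAsFactors = FALSE)
        } else if (stats::runif(1) < config$confounder_rate) {
          ph <- sample(bank[[item]]$confounder, 1L)
          extra <- c(extra, ph)
          rec[[length(rec) + 1L]] <-
            data.frame(doc_id = ids[i], item = item, role = "confounder",
                       phrase = ph, stringsAsFactors = FALSE)
        }
      }
      for (ph in extra) {
        at <- sample.int(length(sentences) + 1L, 1L)
        sentences <- append(sentences, ph, after = at - 1L)
      }
      texts[i] <- paste0(paste(sentences, collapse = ". "), ".")
      planted[[i]] <- if (length(rec)) do.call(rbind, rec) else NULL
    }

    corpus <- data.frame(doc_id = ids, text = texts, journal = journals,
                         stringsAsFactors = FALSE)
    corpus$record_date <- dates
    class(corpus) <- c("rob_corpus", "data.frame")
    class(gold) <- c("rob_gold", "data.frame")
    planted <- do.call(rbind, c(
      list(data.frame(doc_id = character(0), item = character(0),
                      role = character(0), phrase = character(0))),
      planted))
    structure(list(corpus = corpus, gold = gold, planted = planted,
                   config = config), class = "synth_corpus")
  })
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf("<synth_corpus> %d documents, hardness %d, seed %d\n",
              nrow(x$corpus), x$config$hardness, x$config$seed))
  for (item in ROB_ITEMS) {
    cat(sprintf("  %-14s %d gold positive\n", item, sum(x$gold[[item]])))
  }
  invisible(x)
}

#' Write a generated corpus to disk
#'
#' Materialises a [generate_corpus()] result as a ready-to-use corpus
#' layout: `<dir>/texts/<doc_id>.txt`, `<dir>/metadata.csv` and
#' `<dir>/gold.csv`, suitable for [load_corpus()] / [load_gold()].
#'
#' @param x a `synth_corpus`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_corpus <- function(x, dir) {
  if (!inherits(x, "synth_corpus")) abort("`x` must be a synth_corpus")
  text_dir <- file.path(dir, "texts")
  dir.create(text_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(x$corpus))) {
    writeLines(x$corpus$text[i],
               file.path(text_dir, paste0(x$corpus$doc_id[i], ".txt")))
  }
  meta <- data.frame(doc_id = x$corpus$doc_id, journal = x$corpus$journal,
                     record_date = format(x$corpus$record_date),
                     stringsAsFactors = FALSE)
  write_table(meta, file.path(dir, "metadata.csv"))
  write_table(as.data.frame(x$gold), file.path(dir, "gold.csv"))
  invisible(dir)
}

#' Benchmark a pattern set on a synthetic corpus
#'
#' One-call generate / classify / evaluate pipeline. Reports the full
#' diagnostic-accuracy table and whether each item clears the consensus
#' usefulness threshold of sensitivity and specificity both at least 0.80.
#'
#' @param config a [synth_config()].
#' @param patterns an `rob_patterns` object; default the shipped lexicon.
#' @param threshold minimum acceptable sensitivity and specificity
#'   (default 0.80).
#' @return List of class `rob_benchmark`: `report` (the
#'   [evaluate_calls()] table), `pass` (named logical per item),
#'   `min_sens_spec` (named numeric per item), `threshold`, `config`.
#' @export
benchmark <- function(config = synth_config(),
                      patterns = default_patterns(), threshold = 0.80) {
  gen <- generate_corpus(config)
  calls <- classify_corpus(gen$corpus, patterns)
  report <- evaluate_calls(calls, gen$gold)
  mm <- pmin(ifelse(is.na(report$sensitivity), 0, report$sensitivity),
             ifelse(is.na(report$specificity), 0, report$specificity))
  names(mm) <- report$item
  structure(list(report = report, pass = mm >= threshold,
                 min_sens_spec = mm, threshold = threshold,
                 config = config), class = "rob_benchmark")
}

#' @export
print.rob_benchmark <- function(x, ...) {
  cat(sprintf("<rob_benchmark> n=%d, hardness %d, confounder rate %.2f\n",
              x$config$n_docs, x$config$hardness, x$config$confounder_rate))
  for (item in names(x$pass)) {
    r <- x$report[x$report$item == item, ]
    cat(sprintf("  %-14s Se %.2f  Sp %.2f  Acc %.2f  -> %s (threshold %.2f)\n",
                item, r$sensitivity, r$specificity, r$accuracy,
                if (x$pass[[item]]) "pass" else "FAIL", x$threshold))
  }
  invisible(x)
}
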