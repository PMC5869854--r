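#' Detect risk-of-bias reporting in one document
#'
#' Applies one item's inclusion and exclusion patterns to a document and
#' returns a boolean call with auditable evidence. The text is first passed
#' through [normalize_text()]. Every inclusion-pattern match whose character
#' span overlaps an exclusion-pattern match is suppressed; the call is
#' `TRUE` iff at least one inclusion match survives. All surviving matches
#' are returned as evidence, in ascending start order, each with a snippet
#' of up to 60 characters of context on either side.
#'
#' Evidence offsets are 1-based inclusive positions in the *normalized*
#' text (the `substring()` convention); `normalize_text()`'s offset map
#' projects them back to the original file.
#'
#' @param text a single character string (raw manuscript text), or a
#'   one-row corpus slice from [load_corpus()].
#' @param patterns an `rob_patterns` object from [read_patterns()] /
#'   [default_patterns()].
#' @param item one of `"randomization"`, `"blinding"`, `"samplesize"`.
#' @param doc_id optional document identifier carried into the result.
#' @return An object of class `rob_call`: list with `doc_id`, `item`,
#'   `call` (logical) and `evidence` (data frame with columns `pattern_id`,
#'   `start`, `end`, `snippet`; zero rows iff the call is `FALSE`).
#' @examples
#' detect("Animals were randomly allocated to treatment groups.",
#'        default_patterns(), "randomization")$call
#' detect("cDNA was synthesized using random hexamer primers.",
#'        default_patterns(), "randomization")$call
#' @export
detect <- function(text, patterns, item, doc_id = NA_character_) {
  check_item(item)
  if (!inherits(patterns, "rob_patterns")) {
    abort("`patterns` must be an rob_patterns object (see read_patterns())")
  }
  if (is.data.frame(text)) {
    if (nrow(text) != 1L) abort("pass exactly one document to detect()")
    doc_id <- text$doc_id
    text <- text$text
  }
  nt <- normalize_text(text)
  ev <- surviving_matches(nt$text, patterns[[item]])
  ev$snippet <- snippet_at(nt$text, ev$start, ev$end)
  structure(list(doc_id = doc_id, item = item,
                 call = nrow(ev) > 0L, evidence = ev),
            class = "rob_call")
}

# All matches of one PCRE pattern in `text` as a start/end (1-based,
# inclusive) data frame.
pattern_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Inclusion matches not overlapped by any exclusion match, evidence order.
surviving_matches <- function(norm_text, item_patterns) {
  inc <- do.call(rbind, c(
    list(data.frame(pattern_id = character(0), start = integer(0),
                    end = integer(0))),
    lapply(names(item_patterns$include), function(id) {
      hits <- pattern_matches(item_patterns$include[[id]], norm_text)
      if (nrow(hits)) cbind(pattern_id = id, hits) else NULL
    })))
  if (nrow(inc) == 0L) return(inc)
  exc <- do.call(rbind, c(
    list(data.frame(start = integer(0), end = integer(0))),
    lapply(unname(item_patterns$exclude), pattern_matches,
           text = norm_text)))
  if (nrow(exc)) {
    suppressed <- vapply(seq_len(nrow(inc)), function(i) {
      any(inc$start[i] <= exc$end & exc$start <= inc$end[i])
    }, logical(1))
    inc <- inc[!suppressed, , drop = FALSE]
  }
  inc <- inc[order(inc$start, inc$end, inc$pattern_id), , drop = FALSE]
  rownames(inc) <- NULL
  inc
}

snippet_at <- function(text, start, end, context = 60L) {
  if (length(start) == 0L) return(character(0))
  substring(text, pmax(1L, start - context),
            pmin(nchar(text), end + context))
}

#' @export
print.rob_call <- function(x, ...) {
  cat(sprintf("<rob_call> %s  %s: %s (%d evidence span%s)\n",
              x$doc_id %||% "?", x$item, x$call, nrow(x$evidence),
              if (nrow(x$evidence) == 1L) "" else "s"))
  if (nrow(x$evidence)) {
    for (i in seq_len(min(3L, nrow(x$evidence)))) {
      cat(sprintf("  [%s %d-%d] ...%s...\n", x$evidence$pattern_id[i],
                  x$evidence$start[i], x$evidence$end[i],
                  x$evidence$snippet[i]))
    }
  }
  invisible(x)
}

#' Classify every document in a corpus for all three items
#'
#' Runs [detect()] for each of the three risk-of-bias items over every
#' document, yielding exactly three calls per document. Output is
#' deterministic and ordered by `doc_id`, then item (randomization,
#' blinding, samplesize), so repeated runs on identical input are
#' byte-identical when written out.
#'
#' @param corpus a corpus data frame from [load_corpus()] (columns `doc_id`,
#'   `text`, and optionally `journal`, `record_date`).
#' @param patterns an `rob_patterns` object; defaults to the shipped seed
#'   lexicon.
#' @return A data frame of class `rob_calls` with columns `doc_id`, `item`,
#'   `call` (logical), `n_matches` (surviving evidence spans) and
#'   `first_snippet` (context around the first span; `""` for negative
#'   calls).
#' @export
classify_corpus <- function(corpus, patterns = default_patterns()) {
  if (!is.data.frame(corpus) || !all(c("doc_id", "text") %in% names(corpus))) {
    abort("`corpus` must be a data frame with columns doc_id and text")
  }
  missing <- setdiff(ROB_ITEMS, names(patterns))
  if (length(missing)) {
    abort("pattern sets missing for item(s): ", paste(missing, collapse = ", "))
  }
  corpus <- corpus[order(corpus$doc_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    nt <- normalize_text(corpus$text[i])
    per_item <- lapply(ROB_ITEMS, function(item) {
      ev <- surviving_matches(nt$text, patterns[[item]])
      data.frame(doc_id = corpus$doc_id[i], item = item,
                 call = nrow(ev) > 0L, n_matches = nrow(ev),
                 first_snippet = if (nrow(ev)) {
                   snippet_at(nt$text, ev$start[1L], ev$end[1L])
                 } else "",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_item)
  })
  calls <- do.call(rbind, c(
    list(data.frame(doc_id = character(0), item = character(0),
                    call = logical(0), n_matches = integer(0),
                    first_snippet = character(0))),
    rows))
  rownames(calls) <- NULL
  class(calls) <- c("rob_calls", "data.frame")
  calls
}
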