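#' Load a full-text corpus
#'
#' Reads a screening-defined corpus: a metadata CSV (columns `doc_id`,
#' `journal`, `record_date`) plus a directory of UTF-8 plain-text files
#' named `<doc_id>.txt`. The corpus is defined by the metadata (the
#' screening record), not by the file system: metadata rows whose full text
#' is missing are reported — mirroring the gap between records identified
#' and full texts retrieved in real reviews — and files with no metadata
#' row are ignored with a warning. Text content is read verbatim except
#' that line endings are normalized to `"\n"`.
#'
#' @param text_dir directory containing `<doc_id>.txt` files.
#' @param metadata_path CSV with header `doc_id,journal,record_date`;
#'   `record_date` must be ISO-8601 (`YYYY-MM-DD`). `journal` may be empty.
#' @return A data frame of class `rob_corpus`, sorted by `doc_id`, with
#'   columns `doc_id`, `text`, `journal`, `record_date` (`Date`).
#'   Attributes `missing_text` and `unlisted_files` record the reported
#'   discrepancies.
#' @export
load_corpus <- function(text_dir, metadata_path) {
  if (!dir.exists(text_dir)) abort("text directory not found: ", text_dir)
  meta <- tryCatch(
    utils::read.csv(metadata_path, colClasses = "character"),
    error = function(e) abort("cannot read metadata table '", metadata_path,
                              "': ", conditionMessage(e)),
    warning = function(w) abort("cannot read metadata table '", metadata_path,
                                "': ", conditionMessage(w)))
  need <- c("doc_id", "journal", "record_date")
  if (!all(need %in% names(meta))) {
    abort("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(meta$doc_id)) {
    abort("duplicate doc_id in metadata: ",
          paste(unique(meta$doc_id[duplicated(meta$doc_id)]), collapse = ", "))
  }
  dates <- if (nrow(meta)) parse_iso_date(meta$record_date, "record_date") else
    as.Date(character(0))

  files <- list.files(text_dir, pattern = "\\.txt$")
  file_ids <- sub("\\.txt$", "", files)
  unlisted <- setdiff(file_ids, meta$doc_id)
  if (length(unlisted)) {
    warning(length(unlisted), " text file(s) without a metadata row ignored: ",
            paste(utils::head(unlisted, 5), collapse = ", "),
            if (length(unlisted) > 5) ", ..." else "", call. = FALSE)
  }
  have <- meta$doc_id %in% file_ids
  missing <- meta$doc_id[!have]
  if (length(missing)) {
    warning("missing full text for ", length(missing), " of ", nrow(meta),
            " metadata row(s): ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", call. = FALSE)
  }
  corpus <- data.frame(doc_id = meta$doc_id[have],
                       text = vapply(meta$doc_id[have], function(id) {
                         read_text_file(file.path(text_dir, paste0(id, ".txt")))
                       }, character(1), USE.NAMES = FALSE),
                       journal = meta$journal[have],
                       stringsAsFactors = FALSE)
  corpus$record_date <- dates[have]
  corpus <- corpus[order(corpus$doc_id), , drop = FALSE]
  rownames(corpus) <- NULL
  structure(corpus, missing_text = missing, unlisted_files = unlisted,
            class = c("rob_corpus", "data.frame"))
}

# Whole file as one string; CRLF/CR normalized to LF, no other mutation.
read_text_file <- function(path) {
  size <- file.info(path)$size
  txt <- readChar(path, size, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  gsub("\r\n?", "\n", txt)
}

#' Load gold-standard annotations
#'
#' Reads manual ("gold standard") ascertainment of reporting: one row per
#' document with boolean columns for each risk-of-bias item. Accepted
#' boolean tokens are `true/false`, `1/0` and `yes/no` (any case); anything
#' else is an error naming the offending row and column.
#'
#' @param path CSV with header `doc_id,randomization,blinding,samplesize`.
#' @return A data frame of class `rob_gold` with `doc_id` (character) and
#'   three logical columns, sorted by `doc_id`.
#' @export
load_gold <- function(path) {
  gold <- tryCatch(
    utils::read.csv(path, colClasses = "character"),
    error = function(e) abort("cannot read gold table '", path, "': ",
                              conditionMessage(e)),
    warning = function(w) abort("cannot read gold table '", path, "': ",
                                conditionMessage(w)))
  need <- c("doc_id", ROB_ITEMS)
  if (!all(need %in% names(gold))) {
    abort("gold table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(gold$doc_id)) {
    abort("duplicate doc_id in gold table: ",
          paste(unique(gold$doc_id[duplicated(gold$doc_id)]), collapse = ", "))
  }
  for (item in ROB_ITEMS) {
    gold[[item]] <- if (nrow(gold)) parse_bool_token(gold[[item]], item) else
      logical(0)
  }
  gold <- gold[order(gold$doc_id), need, drop = FALSE]
  rownames(gold) <- NULL
  structure(gold, class = c("rob_gold", "data.frame"))
}

#' Write and re-read result tables
#'
#' All result tables are comma-separated UTF-8 text with a header row and a
#' stable column order; fields containing delimiters or quotes are quoted,
#' so writing and re-reading reproduces the object. `write_report()` also
#' accepts a `.json` destination for a JSON variant of any report table.
#'
#' @param calls an `rob_calls` data frame from [classify_corpus()]
#'   (columns `doc_id,item,call,n_matches,first_snippet`).
#' @param x any result data frame (evaluation report, prevalence table,
#'   trend table).
#' @param path destination file; an unwritable path is a fatal error.
#' @return `read_calls()` returns the `rob_calls` data frame; writers
#'   return `path` invisibly.
#' @export
write_calls <- function(calls, path) {
  need <- c("doc_id", "item", "call", "n_matches", "first_snippet")
  if (!is.data.frame(calls) || !all(need %in% names(calls))) {
    abort("`calls` must have columns: ", paste(need, collapse = ", "))
  }
  write_table(calls[, need, drop = FALSE], path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  calls <- utils::read.csv(path, colClasses = c(
    doc_id = "character", item = "character", call = "logical",
    n_matches = "integer", first_snippet = "character"))
  class(calls) <- c("rob_calls", "data.frame")
  calls
}

#' @rdname write_calls
#' @export
write_report <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    ok <- tryCatch({
      jsonlite::write_json(x, path, dataframe = "rows", na = "null",
                           digits = NA)
      TRUE
    }, error = function(e) abort("cannot write '", path, "': ",
                                 conditionMessage(e)))
    return(invisible(path))
  }
  write_table(as.data.frame(x), path)
}

write_table <- function(df, path) {
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) abort("cannot write '", path, "': ",
                              conditionMessage(e)),
    warning = function(w) abort("cannot write '", path, "': ",
                                conditionMessage(w)))
  invisible(path)
}
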