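#' @keywords internal
"_PACKAGE"

# Items the detector knows about, in canonical order.
ROB_ITEMS <- c("randomization", "blinding", "samplesize")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(...) stop(..., call. = FALSE)

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from zero),
#' the convention used for all percentage displays in evaluation reports.
#' Base `round()` rounds halves to even, which does not match how summary
#' tables in the systematic-review literature are typically printed.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(86.5, 95.5, 2.5))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

check_item <- function(item) {
  if (length(item) != 1L || !item %in% ROB_ITEMS) {
    abort("`item` must be one of: ", paste(ROB_ITEMS, collapse = ", "))
  }
  item
}

# Strict ISO-8601 date parsing; returns Date or raises naming the offender.
parse_iso_date <- function(x, context = "date") {
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(rep(NA_character_, length(x)))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  bad <- which(!ok | is.na(d))
  if (length(bad)) {
    abort(sprintf("unparseable %s (expected YYYY-MM-DD) in row(s) %s: %s",
                  context, paste(bad, collapse = ", "),
                  paste(unique(x[bad]), collapse = ", ")))
  }
  d
}

# Parse a declared boolean vocabulary: true/false, 1/0, yes/no (any case).
parse_bool_token <- function(x, column, rows = seq_along(x)) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "1", "yes")] <- TRUE
  out[tok %in% c("false", "0", "no")] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    abort(sprintf(
      "unknown boolean token %s in column '%s', row %d (accepted: true/false, 1/0, yes/no)",
      dQuote(x[bad]), column, rows[bad]))
  }
  out
}
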