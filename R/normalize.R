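#' Normalize manuscript text for pattern matching
#'
#' Prepares raw manuscript text for case-insensitive lexicon matching:
#'
#' 1. hyphen–linebreak sequences (`"-\n"`) are joined, repairing words split
#'    across lines by PDF-to-text conversion (`"rando-\nmization"` becomes
#'    `"randomization"`);
#' 2. every run of whitespace (spaces, tabs, newlines) collapses to a single
#'    space, and leading/trailing whitespace is removed;
#' 3. the result is lowercased.
#'
#' An offset map is returned so every character of the normalized text can be
#' projected back to its position in the original: `map[i]` is the 1-based
#' index in `text` of the character that produced normalized position `i`
#' (for a collapsed whitespace run, the run's first character).
#'
#' @param text a single character string (the full manuscript body).
#' @return An object of class `rob_normtext`: a list with elements `text`
#'   (the normalized string) and `map` (integer vector, one entry per
#'   normalized character; empty for empty input).
#' @examples
#' normalize_text("Randomly  Allocated")$text
#' normalize_text("rando-\nmization")$text
#' @export
normalize_text <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    abort("`text` must be a single character string")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n == 0L) {
    return(structure(list(text = "", map = integer(0)),
                     class = "rob_normtext"))
  }
  keep <- rep(TRUE, n)
  hy <- which(chars == "-")
  hy <- hy[hy < n & chars[hy + 1L] == "\n"]
  keep[hy] <- FALSE
  keep[hy + 1L] <- FALSE

  idx <- which(keep)
  ch <- chars[idx]
  ws <- ch %in% c(" ", "\t", "\n", "\r", "\f", "\v")
  ch[ws] <- " "
  # drop every whitespace char whose predecessor (after de-hyphenation) is
  # also whitespace: runs collapse to their first character
  drop_run <- ws & c(FALSE, ws[-length(ws)])
  ch <- ch[!drop_run]
  idx <- idx[!drop_run]
  ws <- ws[!drop_run]
  if (length(ch) && ws[1L]) {
    ch <- ch[-1L]
    idx <- idx[-1L]
    ws <- ws[-1L]
  }
  m <- length(ch)
  if (m && ws[m]) {
    ch <- ch[-m]
    idx <- idx[-m]
  }
  structure(list(text = tolower(paste(ch, collapse = "")), map = idx),
            class = "rob_normtext")
}

#' @export
print.rob_normtext <- function(x, ...) {
  cat("<normalized text>", nchar(x$text), "characters\n")
  invisible(x)
}
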