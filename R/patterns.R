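#' Pattern sets: the editable detection lexicon
#'
#' A pattern set holds, for each risk-of-bias item (`randomization`,
#' `blinding`, `samplesize`), an ordered list of *inclusion* regular
#' expressions (any match proposes a positive call) and *exclusion* regular
#' expressions (a match suppresses any inclusion match whose character span
#' it overlaps — e.g. "random hexamer" neutralises the "random ..." lexicon
#' inside an RT-PCR protocol). Patterns are matched against
#' [normalize_text()] output, so they are written in lowercase and use
#' single spaces.
#'
#' Every pattern is compiled (PCRE) when the set is loaded; a pattern that
#' does not compile is a fatal error at load time, never at detection time.
#'
#' `default_patterns()` loads the seed lexicon shipped with the package
#' (`system.file("extdata", "patterns-default.yml", package = "robscreen")`).
#' It is a deliberately small, fully user-editable starting vocabulary:
#' copy the file, edit it for your literature, and pass the copy to
#' [read_patterns()].
#'
#' @param path path to a YAML pattern configuration: one block per item,
#'   each with `include` and `exclude` arrays of `{id, pattern}` entries.
#' @return An object of class `rob_patterns`: a named list with one entry
#'   per item, each a list with character vectors `include` and `exclude`
#'   (values are pattern strings, names are pattern ids).
#' @examples
#' ps <- default_patterns()
#' names(ps)
#' ps$randomization$include[1]
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) abort("pattern config not found: ", path)
  raw <- yaml::read_yaml(path)
  missing <- setdiff(ROB_ITEMS, names(raw))
  if (length(missing)) {
    abort("pattern config is missing item block(s): ",
          paste(missing, collapse = ", "))
  }
  ps <- lapply(ROB_ITEMS, function(item) {
    block <- raw[[item]]
    list(include = compile_pattern_list(block$include, item, "include"),
         exclude = compile_pattern_list(block$exclude, item, "exclude"))
  })
  names(ps) <- ROB_ITEMS
  structure(ps, class = "rob_patterns", source = path)
}

#' @rdname read_patterns
#' @export
default_patterns <- function() {
  read_patterns(system.file("extdata", "patterns-default.yml",
                            package = "robscreen", mustWork = TRUE))
}

# Turn a list of {id, pattern} entries into a named character vector,
# checking id uniqueness and that every pattern compiles under PCRE.
compile_pattern_list <- function(entries, item, kind) {
  if (is.null(entries) || length(entries) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  ids <- vapply(entries, function(e) as.character(e$id %||% ""), "")
  pats <- vapply(entries, function(e) as.character(e$pattern %||% ""), "")
  if (any(ids == "") || any(pats == "")) {
    abort(sprintf("every %s/%s entry needs both an 'id' and a 'pattern'",
                  item, kind))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate pattern id in %s/%s: %s", item, kind,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (i in seq_along(pats)) {
    ok <- tryCatch({
      regexpr(pats[i], "", perl = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      abort(sprintf("pattern '%s' (%s/%s) does not compile: %s",
                    ids[i], item, kind, pats[i]))
    }
  }
  stats::setNames(pats, ids)
}

#' @export
print.rob_patterns <- function(x, ...) {
  cat("<rob_patterns>\n")
  for (item in names(x)) {
    cat(sprintf("  %-14s %d include, %d exclude\n", item,
                length(x[[item]]$include), length(x[[item]]$exclude)))
  }
  invisible(x)
}
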