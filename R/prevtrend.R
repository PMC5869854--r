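#' Epoch specification for time binning
#'
#' Trend analyses bin documents by record date in one of two modes:
#'
#' * `fixed_width`: calendar bins of `width_months` months counted
#'   backwards from `anchor_date` (typically the search date). Epoch 0 is
#'   the most recent, covering `(anchor - width, anchor]`; epoch `e` covers
#'   `(anchor - (e+1)*width, anchor - e*width]`. Month arithmetic moves by
#'   calendar months and clamps the day of month (an anchor of Oct-31
#'   stepped back 6 months gives Apr-30).
#' * `quantile`: `n_bins` groups of as-equal-as-possible size in date
#'   order (e.g. quartiles of accession date). Documents sharing an
#'   identical date always land in the same bin: a date's bin is the
#'   provisional bin of its first occurrence in date order, so bin sizes
#'   may differ when ties cross a boundary.
#'
#' @param mode `"fixed_width"` or `"quantile"`.
#' @param width_months bin width in months (`fixed_width`; default 6).
#' @param n_bins number of bins (`quantile`; default 4, i.e. quartiles).
#' @param anchor_date `Date` (or `YYYY-MM-DD` string) the fixed-width bins
#'   count back from; required in `fixed_width` mode.
#' @return Object of class `epoch_spec`.
#' @export
epoch_spec <- function(mode = c("fixed_width", "quantile"),
                       width_months = 6, n_bins = 4, anchor_date = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_width") {
    if (is.null(anchor_date)) abort("fixed_width mode needs `anchor_date`")
    anchor_date <- as.Date(anchor_date)
    if (is.na(anchor_date)) abort("`anchor_date` is not a valid date")
    if (width_months < 1) abort("`width_months` must be >= 1")
  } else {
    if (n_bins < 2) abort("`n_bins` must be >= 2")
  }
  structure(list(mode = mode, width_months = as.integer(width_months),
                 n_bins = as.integer(n_bins), anchor_date = anchor_date),
            class = "epoch_spec")
}

days_in_month <- function(year, month) {
  first_next <- as.Date(sprintf("%04d-%02d-01",
                                year + (month == 12L),
                                ifelse(month == 12L, 1L, month + 1L)))
  as.integer(format(first_next - 1L, "%d"))
}

# `date` minus `m` calendar months, clamping day-of-month.
months_before <- function(date, m) {
  lt <- as.POSIXlt(date)
  total <- (lt$year + 1900L) * 12L + lt$mon - as.integer(m)
  y <- total %/% 12L
  mo <- total %% 12L + 1L
  day <- pmin(lt$mday, days_in_month(y, mo))
  as.Date(sprintf("%04d-%02d-%02d", y, mo, day))
}

#' Assign documents to time epochs
#'
#' @param dates a `Date` vector (document record dates); no `NA`s.
#' @param spec an [epoch_spec()].
#' @return Data frame with one row per date: `epoch` (integer; in
#'   `fixed_width` mode 0 = most recent, in `quantile` mode 0 = oldest
#'   bin), `epoch_index` (integer, always ascending in time: oldest = 0,
#'   most recent = highest — the regression axis), and `label`.
#' @examples
#' sp <- epoch_spec("fixed_width", width_months = 6,
#'                  anchor_date = "2016-10-04")
#' assign_epoch(as.Date(c("2016-09-01", "2016-03-01")), sp)$epoch
#' @export
assign_epoch <- function(dates, spec) {
  if (!inherits(spec, "epoch_spec")) abort("`spec` must be an epoch_spec")
  dates <- as.Date(dates)
  if (length(dates) == 0L) {
    return(data.frame(epoch = integer(0), epoch_index = integer(0),
                      label = character(0)))
  }
  if (anyNA(dates)) abort("epoch assignment needs valid dates (NA found)")
  if (spec$mode == "fixed_width") {
    anchor <- spec$anchor_date
    w <- spec$width_months
    if (any(dates > anchor)) {
      abort("date(s) after the anchor_date (", format(anchor), "): ",
            paste(format(utils::head(dates[dates > anchor], 3)),
                  collapse = ", "))
    }
    J <- 1L
    while (months_before(anchor, J * w) >= min(dates)) J <- J + 1L
    bounds <- vapply(0:J, function(j) months_before(anchor, j * w),
                     as.Date(NA))  # descending: anchor, anchor-w, ...
    asc <- rev(bounds)
    i <- findInterval(as.numeric(dates), as.numeric(asc), left.open = TRUE)
    epoch <- J - i
    label <- sprintf("(%s, %s]",
                     format(as.Date(bounds[epoch + 2L], origin = "1970-01-01")),
                     format(as.Date(bounds[epoch + 1L], origin = "1970-01-01")))
    data.frame(epoch = epoch, epoch_index = max(epoch) - epoch,
               label = label, stringsAsFactors = FALSE)
  } else {
    n <- length(dates)
    sorted <- sort(dates)
    first_rank <- match(dates, sorted)      # first occurrence in date order
    bin <- as.integer(ceiling(first_rank * spec$n_bins / n))
    # describe each occupied bin by its date range
    lab <- vapply(sort(unique(bin)), function(b) {
      sprintf("Q%d: %s to %s", b, format(min(dates[bin == b])),
              format(max(dates[bin == b])))
    }, "")
    names(lab) <- as.character(sort(unique(bin)))
    data.frame(epoch = bin - 1L, epoch_index = bin - 1L,
               label = unname(lab[as.character(bin)]),
               stringsAsFactors = FALSE)
  }
}

# Normalise calls (long) or gold (wide) input into doc_id/item/positive.
positives_long <- function(x) {
  if (all(c("doc_id", "item", "call") %in% names(x))) {
    data.frame(doc_id = x$doc_id, item = x$item, positive = x$call,
               stringsAsFactors = FALSE)
  } else if (all(c("doc_id", ROB_ITEMS) %in% names(x))) {
    do.call(rbind, lapply(ROB_ITEMS, function(item) {
      data.frame(doc_id = x$doc_id, item = item, positive = x[[item]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    abort("expected detector calls (doc_id,item,call) or gold annotations")
  }
}

#' Reporting prevalence by corpus, journal, or time epoch
#'
#' Summarises the proportion of documents calling (or annotated) positive
#' for each item, with exact Clopper\enc{–}{-}Pearson intervals, either for
#' the whole corpus, per journal, or per time epoch. Journal groups smaller
#' than `min_group_size` (default 5, the usual "five or more relevant
#' manuscripts" display rule) are excluded from the ranked list but pooled
#' into a single `"other"` row, so counts are conserved. Journal rows are
#' ranked by proportion descending, ties broken by group label ascending.
#'
#' @param x detector calls ([classify_corpus()]) or gold annotations
#'   ([load_gold()]).
#' @param corpus the corpus data frame (supplies `journal` and
#'   `record_date`); required for journal and epoch grouping.
#' @param group_by `"all"`, `"journal"`, or `"epoch"`.
#' @param spec an [epoch_spec()] (epoch grouping only).
#' @param min_group_size minimum group size for a ranked journal row;
#'   default 5 for journal grouping, 1 otherwise.
#' @param items items to summarise; default all three.
#' @param level confidence level; default 0.95.
#' @return Data frame of class `rob_prevalence` with columns `group_label`,
#'   `item`, `k`, `n`, `proportion`, `ci_low`, `ci_high`, plus
#'   `epoch_index` for epoch grouping.
#' @export
group_prevalence <- function(x, corpus = NULL,
                             group_by = c("all", "journal", "epoch"),
                             spec = NULL, min_group_size = NULL,
                             items = ROB_ITEMS, level = 0.95) {
  group_by <- match.arg(group_by)
  min_group_size <- min_group_size %||% if (group_by == "journal") 5L else 1L
  if (min_group_size < 1L) abort("`min_group_size` must be >= 1")
  long <- positives_long(x)
  long <- long[long$item %in% items, , drop = FALSE]

  if (group_by == "all") {
    groups <- data.frame(doc_id = unique(long$doc_id), group_label = "all",
                         stringsAsFactors = FALSE)
  } else {
    if (is.null(corpus)) abort("`corpus` is required for ", group_by,
                               " grouping")
    if (group_by == "journal") {
      groups <- data.frame(doc_id = corpus$doc_id,
                           group_label = corpus$journal,
                           stringsAsFactors = FALSE)
    } else {
      if (is.null(spec)) abort("epoch grouping needs an epoch_spec")
      if (is.null(corpus$record_date) || anyNA(corpus$record_date)) {
        abort("epoch grouping needs valid record dates for every document")
      }
      ep <- assign_epoch(corpus$record_date, spec)
      groups <- data.frame(doc_id = corpus$doc_id, group_label = ep$label,
                           epoch_index = ep$epoch_index,
                           stringsAsFactors = FALSE)
    }
  }
  long <- merge(long, groups, by = "doc_id")

  out <- do.call(rbind, lapply(intersect(ROB_ITEMS, items), function(item) {
    li <- long[long$item == item, , drop = FALSE]
    tally <- function(label, rows, epoch_index = NA_integer_) {
      ci <- clopper_pearson(sum(rows$positive), nrow(rows), level)
      data.frame(group_label = label, item = item, k = ci$k, n = ci$n,
                 proportion = ci$estimate, ci_low = ci$low,
                 ci_high = ci$high, epoch_index = epoch_index,
                 stringsAsFactors = FALSE)
    }
    labs <- unique(li$group_label)
    rows <- lapply(labs, function(g) {
      tally(g, li[li$group_label == g, , drop = FALSE],
            if (group_by == "epoch") li$epoch_index[li$group_label == g][1L]
            else NA_integer_)
    })
    tab <- do.call(rbind, rows)
    if (group_by == "journal") {
      small <- tab$n < min_group_size
      ranked <- tab[!small, , drop = FALSE]
      ranked <- ranked[order(-ranked$proportion, ranked$group_label), ,
                       drop = FALSE]
      if (any(small)) {
        pooled <- tally("other", li[li$group_label %in%
                                      tab$group_label[small], , drop = FALSE])
        ranked <- rbind(ranked, pooled)
      }
      tab <- ranked
    } else if (group_by == "epoch") {
      tab <- tab[order(tab$epoch_index), , drop = FALSE]
    }
    tab
  }))
  if (group_by != "epoch") out$epoch_index <- NULL
  rownames(out) <- NULL
  class(out) <- c("rob_prevalence", "data.frame")
  out
}

#' Least-squares trend in reporting prevalence over epochs
#'
#' Ordinary least squares of epoch prevalence on the time-ascending epoch
#' index (`epoch_index`; most recent epoch = highest index, so a positive
#' slope means improving reporting). The default regression is unweighted;
#' `weighted = TRUE` weights epochs by their document count as a
#' sensitivity analysis. With a constant response the slope is 0, `r²` is
#' reported as 0 and the p-value as `NA` (the zero-slope test is
#' degenerate).
#'
#' @param estimates an epoch-grouped [group_prevalence()] table.
#' @param weighted weight epochs by `n`? Default `FALSE`.
#' @return Data frame of class `rob_trend`, one row per item: `item`,
#'   `slope` (change in proportion per epoch), `intercept`, `r_squared`,
#'   `slope_se`, `p_value`, `n_epochs`, `weighted`.
#' @export
fit_trend <- function(estimates, weighted = FALSE) {
  need <- c("item", "proportion", "epoch_index")
  if (!all(need %in% names(estimates))) {
    abort("`estimates` must be an epoch-grouped prevalence table (columns ",
          paste(need, collapse = ", "), ")")
  }
  out <- do.call(rbind, lapply(unique(estimates$item), function(item) {
    e <- estimates[estimates$item == item, , drop = FALSE]
    e <- e[order(e$epoch_index), , drop = FALSE]
    if (nrow(e) < 3L) {
      abort("trend fitting needs at least 3 epochs (item ", item,
            " has ", nrow(e), ")")
    }
    w <- if (weighted) e$n else NULL
    if (stats::var(e$proportion) == 0) {
      return(data.frame(item = item, slope = 0, intercept = e$proportion[1L],
                        r_squared = 0, slope_se = 0, p_value = NA_real_,
                        n_epochs = nrow(e), weighted = weighted,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(proportion ~ epoch_index, data = e, weights = w)
    # summary() warns on an exactly collinear fit; exact lines are valid input
    sm <- suppressWarnings(summary(fit))
    data.frame(item = item,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r_squared = sm$r.squared,
               slope_se = sm$coefficients[2L, 2L],
               p_value = sm$coefficients[2L, 4L],
               n_epochs = nrow(e), weighted = weighted,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("rob_trend", "data.frame")
  out
}
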