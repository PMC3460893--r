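#' Acquisition-date periods
#'
#' Periods are half-open intervals `[start, end)` so boundary dates are
#' unambiguous: an acquisition dated 1999-12-31 falls in the pre-2000 period
#' and one dated 2000-01-01 in the next. `default_periods()` builds the three
#' standard strata — everything before 2000, 2000 through 2005, and 2006 up to
#' the database extraction date (inclusive).
#'
#' @param label period name used as the stratum label.
#' @param start,end `Date` (or ISO-8601 string); `start` inclusive, `end`
#'   exclusive.
#' @return A one-row tibble (`period_definition`) or a tibble of three
#'   (`default_periods`).
#' @export
period_definition <- function(label, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (!(start < end)) .stop_config("period start must precede end")
  tibble(label = as.character(label), start = start, end = end)
}

#' @rdname period_definition
#' @param date_min earliest date covered by the first period.
#' @param extraction_date last date covered by the final period (the date the
#'   land-records database was extracted).
#' @export
default_periods <- function(date_min = "1951-01-01",
                            extraction_date = "2011-07-20") {
  dplyr::bind_rows(
    period_definition("pre-2000", date_min, "2000-01-01"),
    period_definition("2000-2005", "2000-01-01", "2006-01-01"),
    period_definition("2006-2011", "2006-01-01", as.Date(extraction_date) + 1)
  )
}

.check_periods <- function(periods) {
  stopifnot(all(c("label", "start", "end") %in% names(periods)))
  if (nrow(periods) > 1) {
    p <- periods[order(periods$start), ]
    if (any(p$end[-nrow(p)] > p$start[-1])) .stop_config("periods must not overlap")
  }
  invisible(periods)
}

#' Split a land layer by acquisition period
#'
#' Each record lands in at most one period layer; records without a date are
#' excluded from every period layer (they remain in the all-records layer the
#' caller already holds). Unparseable date strings are counted, warned about,
#' and treated as undated.
#'
#' @param layer a `vector_layer` with an acquisition-date column.
#' @param periods tibble from [default_periods()] / [period_definition()].
#' @param date_col name of the date column.
#' @param date_format format string used when the column is character.
#' @return Named list of `vector_layer`s, one per period label.
#' @export
stratify_by_date <- function(layer, periods = default_periods(),
                             date_col = "acquisition_date",
                             date_format = "%Y-%m-%d") {
  .check_periods(periods)
  if (!date_col %in% names(layer)) {
    .stop_data(sprintf("date column '%s' not found in layer", date_col))
  }
  d <- .parse_dates(layer[[date_col]], date_format)
  out <- lapply(seq_len(nrow(periods)), function(i) {
    sel <- !is.na(d) & d >= periods$start[i] & d < periods$end[i]
    .relayer(layer[sel, , drop = FALSE], layer)
  })
  setNames(out, periods$label)
}

#' Split a land layer by tenure class
#'
#' Partitions records with known tenure into conservation easements and
#' fee-simple acquisitions; records with unknown tenure appear in neither.
#'
#' @param layer a `vector_layer` with a tenure column containing
#'   `"easement"`, `"fee"` or `"unknown"` (NA is treated as unknown).
#' @param tenure_col name of the tenure column.
#' @return Named list with elements `easement` and `fee`.
#' @export
stratify_by_tenure <- function(layer, tenure_col = "tenure") {
  if (!tenure_col %in% names(layer)) {
    .stop_data(sprintf("tenure column '%s' not found in layer", tenure_col))
  }
  ten <- as.character(layer[[tenure_col]])
  list(
    easement = .relayer(layer[!is.na(ten) & ten == "easement", , drop = FALSE], layer),
    fee = .relayer(layer[!is.na(ten) & ten == "fee", , drop = FALSE], layer)
  )
}

# parse an acquisition-date column (Date or character); unparseable strings
# count as undated, with an optional warning
.parse_dates <- function(raw, date_format = "%Y-%m-%d", warn_bad = TRUE) {
  if (inherits(raw, "Date")) return(raw)
  d <- as.Date(rep(NA_character_, length(raw)))
  nonmiss <- !is.na(raw) & nzchar(trimws(as.character(raw)))
  d[nonmiss] <- as.Date(trimws(as.character(raw[nonmiss])), format = date_format)
  bad <- nonmiss & is.na(d)
  if (warn_bad && any(bad)) {
    warn(sprintf("%d record(s) with unparseable dates treated as undated", sum(bad)))
  }
  d
}
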