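#' Parse FAERS-style dates at day, month, or year precision
#'
#' FAERS quarterly ASCII files carry dates as digit strings of length 8
#' (`YYYYMMDD`), 6 (`YYYYMM`) or 4 (`YYYY`). This parser is total: anything
#' that is not a well-formed digit string, or that encodes an impossible
#' calendar combination (month 13, February 30th, ...), is returned as
#' missing rather than raising.
#'
#' @param x character vector of raw date fields (whitespace tolerated).
#' @return A `data.table` with one row per input and columns `year`, `month`,
#'   `day` (integer, `NA` where not encoded) and `precision` (one of
#'   `"day"`, `"month"`, `"year"`, or `NA` for unparseable/missing input).
#'   Invariants: `day` present implies `month` present; `precision == "day"`
#'   rows form valid calendar dates.
#' @examples
#' parse_faers_date(c("20200119", "202001", "2020", "", "20200230"))
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)

  digits <- grepl("^[0-9]+$", x)
  len <- nchar(x)

  i8 <- digits & len == 8L
  i6 <- digits & len == 6L
  i4 <- digits & len == 4L

  if (any(i4)) {
    y <- as.integer(x[i4])
    ok <- y >= 1000L
    year[i4][ok] <- y[ok]
    precision[i4][ok] <- "year"
  }
  if (any(i6)) {
    y <- as.integer(substr(x[i6], 1L, 4L))
    m <- as.integer(substr(x[i6], 5L, 6L))
    ok <- y >= 1000L & m >= 1L & m <= 12L
    year[i6][ok] <- y[ok]
    month[i6][ok] <- m[ok]
    precision[i6][ok] <- "month"
  }
  if (any(i8)) {
    y <- as.integer(substr(x[i8], 1L, 4L))
    m <- as.integer(substr(x[i8], 5L, 6L))
    d <- as.integer(substr(x[i8], 7L, 8L))
    # round-trip through Date to reject impossible calendar combinations
    cand <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
    ok <- !is.na(cand) & y >= 1000L
    year[i8][ok] <- y[ok]
    month[i8][ok] <- m[ok]
    day[i8][ok] <- d[ok]
    precision[i8][ok] <- "day"
  }

  data.table::data.table(year = year, month = month, day = day,
                         precision = precision)
}

#' Convert day-precision parsed dates to Date
#'
#' @param pd a `data.table` as returned by [parse_faers_date()].
#' @return `Date` vector; `NA` wherever precision is not `"day"`.
#' @export
partial_date_as_date <- function(pd) {
  out <- rep(as.Date(NA), nrow(pd))
  i <- !is.na(pd$precision) & pd$precision == "day"
  if (any(i)) {
    out[i] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[i], pd$month[i],
                              pd$day[i]))
  }
  out
}

#' Format Dates as 8-digit FAERS date strings
#' @param d Date vector.
#' @return character vector `YYYYMMDD`; empty string for `NA`.
#' @keywords internal
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}
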