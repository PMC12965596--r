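# FAERS quarterly ASCII dialect: one table per file, "$"-delimited, no quoting,
# first line a header of upper-case field names, dates as (possibly truncated)
# digit strings. Readers accept plain or gzip files and tolerate extra columns.

.faers_schemas <- list(
  demo = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "AGE", "AGE_COD",
           "SEX", "OCCP_COD", "REPORTER_COUNTRY"),
  drug = c("PRIMARYID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME"),
  reac = c("PRIMARYID", "PT"),
  ther = c("PRIMARYID", "DSG_DRUG_SEQ", "START_DT")
)

.role_codes <- c("PS", "SS", "C", "I")

.read_lines_any <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
}

#' Read one FAERS-dialect quarterly table
#'
#' Parses a `"$"`-delimited (configurable) FAERS ASCII table into a typed
#' `data.table`. The header must contain the table kind's required columns;
#' extra columns are ignored. Data lines whose field count does not match the
#' header are dropped, counted, and reported via a message and the
#' `"malformed"` attribute of the result. All values are whitespace-trimmed.
#'
#' @param path file path (plain or `.gz`).
#' @param table_kind one of `"demo"`, `"drug"`, `"reac"`, `"ther"`.
#' @param sep field delimiter, default the FAERS `"$"`.
#' @return a `data.table` with lower-case typed columns:
#'   * demo: `primaryid`, `caseid` (integer), `fda_dt` (`Date`), `event_dt`
#'     (raw character, possibly partial), `age` (numeric), `age_cod`, `sex`,
#'     `occp_cod`, `reporter_country` (character, `NA` when empty);
#'   * drug: `primaryid`, `drug_seq` (integer), `role_cod` (upper-cased),
#'     `drugname`;
#'   * reac: `primaryid`, `pt`;
#'   * ther: `primaryid`, `dsg_drug_seq` (integer), `start_dt` (raw character).
#' @export
read_faers_table <- function(path, table_kind = c("demo", "drug", "reac", "ther"),
                             sep = "$") {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) {
    stop(sprintf("cannot read FAERS table: file '%s' does not exist", path),
         call. = FALSE)
  }
  lines <- .read_lines_any(path)
  if (length(lines) == 0L) {
    stop(sprintf("file '%s' is empty (no header line)", path), call. = FALSE)
  }
  header <- trimws(toupper(strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]))
  required <- .faers_schemas[[table_kind]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema error in '%s': required column(s) %s missing from %s header",
                 path, paste(missing_cols, collapse = ", "),
                 toupper(table_kind)), call. = FALSE)
  }

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, sep, fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad rather than reject
  nf <- lengths(parts)
  pad <- nf == length(header) - 1L & endsWith(body, sep)
  if (any(pad)) {
    parts[pad] <- lapply(parts[pad], function(p) c(p, ""))
    nf[pad] <- length(header)
  }
  ok <- nf == length(header)
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    message(sprintf("%s: dropped %d malformed line(s) (field count != %d)",
                    basename(path), n_malformed, length(header)))
  }
  parts <- parts[ok]

  cols <- lapply(seq_along(header), function(j) {
    trimws(vapply(parts, `[[`, character(1L), j))
  })
  names(cols) <- header
  dt <- data.table::as.data.table(cols[required])
  data.table::setnames(dt, tolower(required))

  out <- switch(table_kind,
    demo = .typed_demo(dt, path),
    drug = .typed_drug(dt),
    reac = .typed_reac(dt),
    ther = .typed_ther(dt)
  )
  data.table::setattr(out, "malformed", n_malformed)
  out
}

.blank_to_na <- function(x) {
  x[!nzchar(x)] <- NA_character_
  x
}

.typed_demo <- function(dt, path) {
  out <- data.table::data.table(
    primaryid = as.integer(dt$primaryid),
    caseid = as.integer(dt$caseid),
    fda_dt = partial_date_as_date(parse_faers_date(dt$fda_dt)),
    event_dt = .blank_to_na(dt$event_dt),
    age = suppressWarnings(as.numeric(dt$age)),
    age_cod = .blank_to_na(toupper(dt$age_cod)),
    sex = .blank_to_na(toupper(dt$sex)),
    occp_cod = .blank_to_na(toupper(dt$occp_cod)),
    reporter_country = .blank_to_na(dt$reporter_country)
  )
  if (anyNA(out$fda_dt)) {
    stop(sprintf("'%s': %d DEMO row(s) have FDA_DT that is not a complete date",
                 path, sum(is.na(out$fda_dt))), call. = FALSE)
  }
  if (anyDuplicated(out$primaryid)) {
    stop(sprintf("'%s': PRIMARYID is not unique within the DEMO table", path),
         call. = FALSE)
  }
  out
}

.typed_drug <- function(dt) {
  role <- toupper(dt$role_cod)
  n_unknown <- sum(!(role %in% .role_codes) & nzchar(role))
  if (n_unknown > 0L) {
    message(sprintf("DRUG: %d row(s) carry a role code outside {%s}; preserved but never primary-suspect",
                    n_unknown, paste(.role_codes, collapse = ", ")))
  }
  data.table::data.table(
    primaryid = as.integer(dt$primaryid),
    drug_seq = as.integer(dt$drug_seq),
    role_cod = .blank_to_na(role),
    drugname = dt$drugname
  )
}

.typed_reac <- function(dt) {
  out <- data.table::data.table(
    primaryid = as.integer(dt$primaryid),
    pt = dt$pt
  )
  out[nzchar(out$pt)]
}

.typed_ther <- function(dt) {
  data.table::data.table(
    primaryid = as.integer(dt$primaryid),
    dsg_drug_seq = as.integer(dt$dsg_drug_seq),
    start_dt = .blank_to_na(dt$start_dt)
  )
}

#' Write one FAERS-dialect table
#'
#' Inverse of [read_faers_table()]: writes the typed `data.table` back to the
#' `"$"`-delimited ASCII dialect with upper-case headers and 8-digit dates.
#'
#' @param dt typed table as produced by [read_faers_table()] or the synthetic
#'   generator.
#' @param path output file path.
#' @param table_kind one of `"demo"`, `"drug"`, `"reac"`, `"ther"`.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(dt, path, table_kind = c("demo", "drug", "reac", "ther"),
                              sep = "$") {
  table_kind <- match.arg(table_kind)
  required <- .faers_schemas[[table_kind]]
  out <- data.table::copy(data.table::as.data.table(dt))
  if ("fda_dt" %in% names(out) && inherits(out$fda_dt, "Date")) {
    out[, "fda_dt" := format_faers_date(out$fda_dt)]
  }
  for (col in names(out)) {
    v <- out[[col]]
    v <- as.character(v)
    v[is.na(v)] <- ""
    if (any(grepl(sep, v, fixed = TRUE))) {
      stop(sprintf("field '%s' contains the delimiter '%s'; FAERS dialect has no quoting",
                   col, sep), call. = FALSE)
    }
    data.table::set(out, j = col, value = v)
  }
  data.table::setnames(out, toupper(names(out)))
  miss <- setdiff(required, names(out))
  if (length(miss) > 0L) {
    stop(sprintf("cannot write %s table: missing column(s) %s",
                 toupper(table_kind), paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- out[, required, with = FALSE]
  lines <- c(paste(required, collapse = sep),
             do.call(paste, c(as.list(out), sep = sep)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column delimited lookup file (synonyms, PT to SOC map)
#'
#' @param path file path; lines are `key<sep>value` (or a single column for
#'   synonym lists); `#`-prefixed lines and blanks are skipped.
#' @param sep delimiter, default tab.
#' @param n_cols 1 or 2.
#' @return character vector (`n_cols = 1`) or two-column `data.table`
#'   (`key`, `value`).
#' @keywords internal
read_lookup_file <- function(path, sep = "\t", n_cols = 2L) {
  if (!file.exists(path)) {
    stop(sprintf("lookup file '%s' does not exist", path), call. = FALSE)
  }
  lines <- .read_lines_any(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (n_cols == 1L) {
    return(lines)
  }
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop(sprintf("lookup file '%s': %d line(s) lack the '%s' delimiter",
                 path, sum(bad), sep), call. = FALSE)
  }
  out <- data.table::data.table(
    k = trimws(vapply(parts, `[[`, character(1L), 1L)),
    v = trimws(vapply(parts, `[[`, character(1L), 2L))
  )
  data.table::setnames(out, c("key", "value"))
  out
}
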