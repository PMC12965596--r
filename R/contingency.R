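# 2x2 contingency tables for disproportionality analysis.
#
# For a target-drug cohort and one event term:
#   a = cohort reports mentioning the term      b = cohort reports without it
#   c = background reports mentioning the term  d = background reports without it
# Counting unit is the distinct report: a report mentioning a PT twice counts
# once. N = a+b+c+d is identical across terms of one analysis.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer counts.
#' @return list of class `"pv_table"` with fields `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency_table: a, b, c, d must be non-negative integers",
         call. = FALSE)
  }
  n <- a + b + c + d
  if (n <= 0) stop("contingency_table: empty table (N = 0)", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, n = n), class = "pv_table")
}

#' @export
print.pv_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target term", "other terms")))
  print(m)
  invisible(x)
}

#' Build per-term contingency tables for a cohort against the background
#'
#' @param cohort_pairs `data.table(primaryid, term)` of deduplicated
#'   (report, term) pairs for cohort reports.
#' @param background_pairs same for all non-cohort reports.
#' @param n_cohort,n_background total distinct report counts (defaults: number
#'   of distinct `primaryid`s in each pair set; pass explicitly when some
#'   reports carry no term at the analyzed level).
#' @return `data.table(term, a, b, c, d, n)`, one row per term occurring in
#'   either pair set, ordered by descending `a` then term.
#' @export
build_contingency_tables <- function(cohort_pairs, background_pairs,
                                     n_cohort = NULL, n_background = NULL) {
  co <- unique(data.table::as.data.table(cohort_pairs)[, c("primaryid", "term"),
                                                       with = FALSE])
  bg <- unique(data.table::as.data.table(background_pairs)[, c("primaryid", "term"),
                                                           with = FALSE])
  if (is.null(n_cohort)) n_cohort <- data.table::uniqueN(co$primaryid)
  if (is.null(n_background)) n_background <- data.table::uniqueN(bg$primaryid)
  if (n_cohort + n_background == 0L) {
    stop("build_contingency_tables: empty database", call. = FALSE)
  }
  a_tab <- co[, list(a = .N), by = "term"]
  c_tab <- bg[, list(c = .N), by = "term"]
  tab <- merge(a_tab, c_tab, by = "term", all = TRUE)
  tab[is.na(tab$a), "a" := 0L]
  tab[is.na(tab$c), "c" := 0L]
  tab[, "b" := n_cohort - tab$a]
  tab[, "d" := n_background - tab$c]
  tab[, "n" := n_cohort + n_background]
  data.table::setcolorder(tab, c("term", "a", "b", "c", "d", "n"))
  tab[order(-tab$a, tab$term)]
}

#' Observed and expected counts for every drug-event pair in a database
#'
#' Used to fit the gamma-Poisson shrinker prior across the whole database:
#' for each (drug, event) pair, `a` is the number of distinct reports carrying
#' both, and `E = n_drug * n_event / N` is the count expected under
#' independence.
#'
#' @param drug_pairs `data.table(primaryid, drug)` distinct report-drug pairs.
#' @param event_pairs `data.table(primaryid, term)` distinct report-term pairs.
#' @param n_reports total distinct reports in the database (default: union of
#'   `primaryid`s across both inputs).
#' @return `data.table(drug, term, a, e)` for pairs with `a >= 1`.
#' @export
build_pair_expected <- function(drug_pairs, event_pairs, n_reports = NULL) {
  dp <- unique(data.table::as.data.table(drug_pairs)[, c("primaryid", "drug"),
                                                     with = FALSE])
  ep <- unique(data.table::as.data.table(event_pairs)[, c("primaryid", "term"),
                                                      with = FALSE])
  if (is.null(n_reports)) {
    n_reports <- data.table::uniqueN(c(dp$primaryid, ep$primaryid))
  }
  joint <- merge(dp, ep, by = "primaryid", allow.cartesian = TRUE)
  a_tab <- joint[, list(a = .N), by = c("drug", "term")]
  n_drug <- dp[, list(n_drug = .N), by = "drug"]
  n_event <- ep[, list(n_event = .N), by = "term"]
  a_tab <- merge(a_tab, n_drug, by = "drug")
  a_tab <- merge(a_tab, n_event, by = "term")
  a_tab[, "e" := a_tab$n_drug * a_tab$n_event / n_reports]
  out <- a_tab[, c("drug", "term", "a", "e"), with = FALSE]
  out[order(out$drug, out$term)]
}
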