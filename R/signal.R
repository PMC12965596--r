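# Per-term signal metrics and the conjunctive four-algorithm gate.
#
# A drug-event pair is declared a signal only when ALL four algorithms pass
# their thresholds (and the raw count clears a minimum), which is the
# conservative convention in spontaneous-report screening:
#   a >= min_a;  ROR CI lower bound > 1;  PRR >= 2 with chi2 >= 4;
#   IC025 > 0;  EBGM05 > 2.

#' Signal threshold set
#'
#' Defaults are the field-standard conjunctive criteria
#' `(min_a = 3, ror_lo > 1, prr >= 2 & chi2 >= 4, ic025 > 0, ebgm05 > 2)`;
#' every component is configurable.
#'
#' @param min_a minimum report count.
#' @param ror_lo_gt strict lower bound for the ROR CI lower limit.
#' @param prr_ge,chi2_ge PRR and chi-squared thresholds (non-strict).
#' @param ic025_gt strict lower bound for IC025.
#' @param ebgm05_gt strict lower bound for EBGM05.
#' @return list of class `"signal_thresholds"`.
#' @export
signal_thresholds <- function(min_a = 3, ror_lo_gt = 1, prr_ge = 2,
                              chi2_ge = 4, ic025_gt = 0, ebgm05_gt = 2) {
  vals <- c(min_a = min_a, ror_lo_gt = ror_lo_gt, prr_ge = prr_ge,
            chi2_ge = chi2_ge, ic025_gt = ic025_gt, ebgm05_gt = ebgm05_gt)
  if (any(!is.finite(vals))) {
    stop("signal_thresholds: all thresholds must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "signal_thresholds")
}

#' Compute the full metric set for a table of per-term counts
#'
#' @param tables `data.table(term, a, b, c, d, n)` from
#'   [build_contingency_tables()].
#' @param prior a fitted `"gps_prior"` for the EBGM component.
#' @param thresholds a [signal_thresholds()] set.
#' @param correct_chi2 Yates correction flag, passed to [prr_stat()].
#' @return `data.table` with one row per term: counts, `ror/ror_lo/ror_hi`,
#'   `prr/chi2`, `ic/ic025`, `ebgm/ebgm05`, per-algorithm flags
#'   (`flag_ror`, `flag_prr`, `flag_ic`, `flag_ebgm`), and the conjunctive
#'   `positive` verdict.
#' @export
compute_signal_metrics <- function(tables, prior,
                                   thresholds = signal_thresholds(),
                                   correct_chi2 = TRUE) {
  tab <- data.table::as.data.table(tables)
  stopifnot(all(c("term", "a", "b", "c", "d", "n") %in% names(tab)))
  ror <- ror_stat(tab$a, tab$b, tab$c, tab$d)
  prr <- prr_stat(tab$a, tab$b, tab$c, tab$d, correct = correct_chi2)
  ic <- bcpnn_ic(tab$a, tab$b, tab$c, tab$d)
  eb <- ebgm_stat(tab$a, ic$e, prior)

  out <- data.table::data.table(
    term = tab$term, a = tab$a, b = tab$b, c = tab$c, d = tab$d, n = tab$n,
    e = ic$e,
    ror = ror$ror, ror_lo = ror$ror_lo, ror_hi = ror$ror_hi,
    prr = prr$prr, chi2 = prr$chi2,
    ic = ic$ic, ic025 = ic$ic025,
    ebgm = eb$ebgm, ebgm05 = eb$ebgm05
  )
  out[, "flag_ror" := !is.na(out$ror_lo) & out$ror_lo > thresholds$ror_lo_gt]
  out[, "flag_prr" := !is.na(out$prr) & !is.na(out$chi2) &
        out$prr >= thresholds$prr_ge & out$chi2 >= thresholds$chi2_ge]
  out[, "flag_ic" := !is.na(out$ic025) & out$ic025 > thresholds$ic025_gt]
  out[, "flag_ebgm" := !is.na(out$ebgm05) & out$ebgm05 > thresholds$ebgm05_gt]
  out[, "positive" := out$a >= thresholds$min_a & out$flag_ror &
        out$flag_prr & out$flag_ic & out$flag_ebgm]
  out
}

#' Evaluate the conjunctive signal gate for one metric row
#'
#' @param metrics a one-row slice of the [compute_signal_metrics()] output
#'   (or any list with fields `a`, `ror_lo`, `prr`, `chi2`, `ic025`,
#'   `ebgm05`).
#' @param thresholds a [signal_thresholds()] set.
#' @return logical verdict, with attribute `"reason"` naming the first
#'   failing (or undefined) component when negative.
#' @export
evaluate_signal <- function(metrics, thresholds = signal_thresholds()) {
  comp <- list(
    min_count = !is.na(metrics$a) && metrics$a >= thresholds$min_a,
    ror = !is.na(metrics$ror_lo) && metrics$ror_lo > thresholds$ror_lo_gt,
    prr = !is.na(metrics$prr) && !is.na(metrics$chi2) &&
      metrics$prr >= thresholds$prr_ge && metrics$chi2 >= thresholds$chi2_ge,
    ic = !is.na(metrics$ic025) && metrics$ic025 > thresholds$ic025_gt,
    ebgm = !is.na(metrics$ebgm05) && metrics$ebgm05 > thresholds$ebgm05_gt
  )
  verdict <- all(unlist(comp))
  if (!verdict) {
    failing <- names(comp)[!unlist(comp)]
    undefined <- c(
      if (is.na(metrics$ror_lo)) "ror_undefined",
      if (is.na(metrics$prr)) "prr_undefined",
      if (is.na(metrics$ic025)) "ic_undefined",
      if (is.na(metrics$ebgm05)) "ebgm_undefined"
    )
    attr(verdict, "reason") <- paste(unique(c(undefined, failing)),
                                     collapse = ",")
  }
  verdict
}

#' Write / read a signal table as delimited text
#'
#' Columns mirror the published layout: term, count, the four statistics with
#' their interval bounds, per-algorithm flags, and the conjunctive verdict.
#' The reader round-trips what the writer produced.
#'
#' @param metrics output of [compute_signal_metrics()].
#' @param path output path.
#' @param digits significant digits for floating-point columns (default 6;
#'   fixed so identical runs are byte-identical).
#' @return `path` invisibly (writer); a `data.table` (reader).
#' @export
write_signal_table <- function(metrics, path, digits = 6) {
  out <- data.table::copy(data.table::as.data.table(metrics))
  num <- names(out)[vapply(out, is.double, logical(1L))]
  for (col in num) {
    data.table::set(out, j = col, value = signif(out[[col]], digits))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_signal_table
#' @export
read_signal_table <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA")
}
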