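# Frequentist disproportionality statistics: reporting odds ratio (ROR),
# proportional reporting ratio (PRR) with its chi-squared companion, and the
# BCPNN information component (IC) in its shrinkage observed/expected form.
# All three are vectorized over the count columns so whole signal tables are
# computed in one call.

#' Reporting odds ratio with log-normal 95% CI
#'
#' `ROR = ad / bc`; `CI = exp(log ROR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' No continuity correction is applied: any zero cell yields `NA` with an
#' explanatory `reason`, rather than a manufactured finite value.
#'
#' @param a,b,c,d count vectors (recycled).
#' @return `data.table(ror, ror_lo, ror_hi, reason)`; `reason` is `NA` when
#'   defined, `"zero_cell"` otherwise.
#' @export
ror_stat <- function(a, b, c, d) {
  m <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), m); b <- rep_len(as.numeric(b), m)
  c <- rep_len(as.numeric(c), m); d <- rep_len(as.numeric(d), m)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ror_lo <- ror_hi <- rep(NA_real_, length(ok))
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  est <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  ror[ok] <- est
  ror_lo[ok] <- exp(log(est) - 1.96 * se)
  ror_hi[ok] <- exp(log(est) + 1.96 * se)
  data.table::data.table(ror = ror, ror_lo = ror_lo, ror_hi = ror_hi,
                         reason = ifelse(ok, NA_character_, "zero_cell"))
}

#' Proportional reporting ratio and Yates-corrected chi-squared
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`. The companion statistic is the Pearson
#' chi-squared on the 2x2 with Yates continuity correction,
#' `chi2 = N (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' which is exactly zero at exact independence. Set `correct = FALSE` for the
#' uncorrected statistic.
#'
#' @param a,b,c,d count vectors.
#' @param correct apply Yates continuity correction (default `TRUE`).
#' @return `data.table(prr, chi2, reason)`; `prr` is `NA` with reason
#'   `"zero_background"` when `c = 0` (or a margin is empty).
#' @export
prr_stat <- function(a, b, c, d, correct = TRUE) {
  # doubles: 2x2 margin products overflow 32-bit integers at FAERS scale
  m <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), m); b <- rep_len(as.numeric(b), m)
  c <- rep_len(as.numeric(c), m); d <- rep_len(as.numeric(d), m)
  n <- a + b + c + d
  ok <- (a + b) > 0 & (c + d) > 0 & c > 0
  prr <- rep(NA_real_, length(ok))
  prr[ok] <- (a[ok] / (a[ok] + b[ok])) / (c[ok] / (c[ok] + d[ok]))

  margins <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- rep(NA_real_, length(ok))
  okm <- margins > 0
  dev <- abs(a * d - b * c)
  if (correct) dev <- pmax(dev - n / 2, 0)
  chi2[okm] <- n[okm] * dev[okm]^2 / margins[okm]
  data.table::data.table(
    prr = prr, chi2 = chi2,
    reason = ifelse(ok, NA_character_, "zero_background")
  )
}

#' BCPNN information component with closed-form credibility bound
#'
#' With the expected count `E = (a+b)(a+c)/N`, the shrinkage information
#' component is `IC = log2((a + 0.5) / (E + 0.5))`, and its lower 2.5%
#' credibility bound is approximated in closed form as
#' `IC025 = IC - 3.3 (a + 0.5)^(-1/2) - 2.4 (a + 0.5)^(-1)`.
#' This is the deterministic approximation to the 2.5th percentile of
#' `log2(lambda)` under the posterior `lambda ~ Gamma(a + 0.5, E + 0.5)`;
#' the test suite holds it against a Monte-Carlo oracle of that posterior.
#'
#' @param a,b,c,d count vectors; alternatively supply `e` directly.
#' @param e optional expected counts overriding the margin formula.
#' @return `data.table(ic, ic025, e)` in bits.
#' @export
bcpnn_ic <- function(a, b = NULL, c = NULL, d = NULL, e = NULL) {
  a <- as.numeric(a)
  if (is.null(e)) {
    m <- max(length(a), length(b), length(c), length(d))
    a <- rep_len(a, m)
    b <- rep_len(as.numeric(b), m); c <- rep_len(as.numeric(c), m)
    d <- rep_len(as.numeric(d), m)
    n <- a + b + c + d
    if (any(n <= 0)) stop("bcpnn_ic: N must be positive", call. = FALSE)
    e <- (a + b) * (a + c) / n
  }
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2.4 * (a + 0.5)^(-1)
  data.table::data.table(ic = ic, ic025 = ic025, e = e)
}
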