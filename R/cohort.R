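# Case-level deduplication and primary-suspect cohort construction.
#
# FAERS accumulates multiple versions of the same case across quarters; the
# FDA rule keeps, per CASEID, the report with the most recent FDA receipt
# date, breaking ties by the highest PRIMARYID. Both rules collapse to a
# single lexicographic key (CASEID; FDA_DT desc; PRIMARYID desc), which makes
# the operation total, order-invariant and idempotent.

#' Deduplicate safety reports by the FDA case rules
#'
#' @param reports DEMO-style `data.table` with at least `primaryid`, `caseid`,
#'   `fda_dt` (complete `Date`).
#' @return list with:
#'   * `survivors`: the retained rows (one per distinct `caseid`), ordered by
#'     `primaryid`;
#'   * `removed`: `data.table(primaryid, caseid, reason)` with reason
#'     `"older_fda_dt"` or `"lower_primaryid"`.
#' @export
deduplicate_reports <- function(reports) {
  dt <- data.table::as.data.table(reports)
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(dt)))
  if (anyNA(dt$fda_dt)) {
    stop("deduplicate_reports: all fda_dt must be complete dates", call. = FALSE)
  }
  ord <- order(dt$caseid, -as.integer(dt$fda_dt), -dt$primaryid)
  dt_sorted <- dt[ord]
  keep_first <- !duplicated(dt_sorted$caseid)
  survivors <- dt_sorted[keep_first]

  removed_rows <- dt_sorted[!keep_first]
  if (nrow(removed_rows) > 0L) {
    surv_dt <- survivors[, list(caseid, surv_fda_dt = fda_dt)]
    removed_rows <- merge(removed_rows, surv_dt, by = "caseid", sort = FALSE)
    removed <- data.table::data.table(
      primaryid = removed_rows$primaryid,
      caseid = removed_rows$caseid,
      reason = ifelse(removed_rows$fda_dt < removed_rows$surv_fda_dt,
                      "older_fda_dt", "lower_primaryid")
    )
  } else {
    removed <- data.table::data.table(primaryid = integer(), caseid = integer(),
                                      reason = character())
  }
  survivors <- survivors[order(survivors$primaryid)]
  removed <- removed[order(removed$primaryid)]
  list(survivors = survivors, removed = removed)
}

#' Normalize a drug name for matching
#'
#' Upper-cases and replaces every non-alphanumeric character with a space, so
#' that `"Remeron (mirtazapine) 15mg tab"` tokenizes cleanly.
#' @keywords internal
normalize_drugname <- function(x) {
  x <- toupper(x)
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Select the primary-suspect cohort for a target drug
#'
#' A report enters the cohort iff at least one of its DRUG rows has role code
#' `PS` and a drug name matching the synonym list. Matching is
#' case-insensitive on punctuation-stripped names; in the default
#' `"whole_word"` mode a synonym must appear as a full token sequence inside
#' the verbatim name (so embedded doses and brand wrappers are tolerated),
#' while `"substring"` mode accepts any substring hit.
#'
#' @param drug_rows DRUG-style `data.table` (`primaryid`, `role_cod`,
#'   `drugname`).
#' @param synonyms non-empty character vector of names for the target drug.
#' @param mode `"whole_word"` (default) or `"substring"`.
#' @return sorted integer vector of cohort `primaryid`s.
#' @export
select_primary_suspect <- function(drug_rows, synonyms,
                                   mode = c("whole_word", "substring")) {
  mode <- match.arg(mode)
  if (length(synonyms) == 0L || all(!nzchar(trimws(synonyms)))) {
    stop("configuration error: the drug synonym list is empty", call. = FALSE)
  }
  dt <- data.table::as.data.table(drug_rows)
  ps <- dt[!is.na(dt$role_cod) & dt$role_cod == "PS"]
  if (nrow(ps) == 0L) return(integer())
  hit <- match_drugname(ps$drugname, synonyms, mode = mode)
  sort(unique(ps$primaryid[hit]))
}

#' Match verbatim drug names against a synonym list
#'
#' @inheritParams select_primary_suspect
#' @param drugnames character vector of verbatim names.
#' @return logical vector.
#' @export
match_drugname <- function(drugnames, synonyms,
                           mode = c("whole_word", "substring")) {
  mode <- match.arg(mode)
  norm <- normalize_drugname(drugnames)
  syn <- unique(normalize_drugname(synonyms))
  syn <- syn[nzchar(syn)]
  hit <- rep(FALSE, length(norm))
  if (mode == "whole_word") {
    padded <- paste0(" ", norm, " ")
    for (s in syn) {
      hit <- hit | grepl(paste0(" ", s, " "), padded, fixed = TRUE)
    }
  } else {
    for (s in syn) {
      hit <- hit | grepl(s, norm, fixed = TRUE)
    }
  }
  hit
}

#' Load a PT to SOC mapping table
#'
#' MedDRA is licensed and is never bundled: the map is a user-supplied
#' two-column delimited file (`PT<sep>SOC`). Each PT is assumed to carry its
#' primary SOC only.
#'
#' @param path two-column file path.
#' @param sep delimiter, default tab.
#' @param version free-text version label stored on the map.
#' @return a `data.table(pt, soc)` with attribute `"version"`.
#' @export
load_soc_map <- function(path, sep = "\t", version = basename(path)) {
  m <- read_lookup_file(path, sep = sep, n_cols = 2L)
  out <- data.table::data.table(pt = m$key, soc = m$value)
  if (anyDuplicated(out$pt)) {
    stop(sprintf("SOC map '%s' assigns multiple SOCs to one PT", path),
         call. = FALSE)
  }
  data.table::setattr(out, "version", version)
  out
}

#' Load a drug synonym list (one name per line)
#' @param path file path.
#' @return character vector.
#' @export
load_synonyms <- function(path) {
  syn <- read_lookup_file(path, n_cols = 1L)
  if (length(syn) == 0L) {
    stop(sprintf("configuration error: synonym file '%s' is empty", path),
         call. = FALSE)
  }
  syn
}

#' Map preferred terms to system organ classes
#'
#' Every PT maps to exactly one SOC, or to the explicit `"UNMAPPED"` bucket;
#' the number of unmapped terms is reported via a warning and the
#' `"n_unmapped"` attribute.
#'
#' @param pt_list character vector of PTs.
#' @param soc_map map from [load_soc_map()].
#' @return `data.table(pt, soc)` aligned with `pt_list`.
#' @export
map_pt_to_soc <- function(pt_list, soc_map) {
  if (length(pt_list) == 0L) {
    out <- data.table::data.table(pt = character(), soc = character())
    data.table::setattr(out, "n_unmapped", 0L)
    return(out)
  }
  idx <- match(pt_list, soc_map$pt)
  soc <- soc_map$soc[idx]
  unmapped <- is.na(idx)
  soc[unmapped] <- "UNMAPPED"
  n_un <- length(unique(pt_list[unmapped]))
  if (n_un > 0L) {
    warning(sprintf("%d preferred term(s) missing from the SOC map; bucketed as UNMAPPED",
                    n_un), call. = FALSE)
  }
  out <- data.table::data.table(pt = pt_list, soc = soc)
  data.table::setattr(out, "n_unmapped", n_un)
  out
}

#' Age stratum labels
#'
#' Two labeled boundary conventions are supported: `"baseline"` uses
#' `<18`, `18-65` (inclusive both ends), `>65` for descriptive tables;
#' `"subgroup"` uses `<18`, `18-64`, `>=65` for stratified signal runs
#' (age exactly 65 falls in the oldest stratum).
#'
#' @param age_years numeric age in years (NA allowed).
#' @param scheme `"baseline"` or `"subgroup"`.
#' @return character vector of stratum labels; `NA` for missing age.
#' @export
age_stratum <- function(age_years, scheme = c("baseline", "subgroup")) {
  scheme <- match.arg(scheme)
  out <- rep(NA_character_, length(age_years))
  i <- !is.na(age_years)
  if (scheme == "baseline") {
    out[i & age_years < 18] <- "<18"
    out[i & age_years >= 18 & age_years <= 65] <- "18-65"
    out[i & age_years > 65] <- ">65"
  } else {
    out[i & age_years < 18] <- "<18"
    out[i & age_years >= 18 & age_years < 65] <- "18-64"
    out[i & age_years >= 65] <- ">=65"
  }
  out
}

#' Normalize AGE/AGE_COD to years
#'
#' Only `YR` (years) and `DEC` (decades) are converted; other unit codes are
#' carried through as missing for stratification purposes, since only age
#' strata are consumed downstream.
#'
#' @param age numeric AGE value.
#' @param age_cod unit code (`YR`, `DEC`, ...).
#' @return numeric years (NA where not convertible).
#' @export
age_in_years <- function(age, age_cod) {
  out <- rep(NA_real_, length(age))
  cod <- toupper(ifelse(is.na(age_cod), "YR", age_cod))
  i <- !is.na(age)
  out[i & cod == "YR"] <- age[i & cod == "YR"]
  out[i & cod == "DEC"] <- age[i & cod == "DEC"] * 10
  out
}
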