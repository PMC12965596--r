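# Orchestration: baseline characteristics, PT/SOC signal tables, top-K
# selection, sensitivity exclusion, and age-subgroup reanalysis.

#' Round half-up to one decimal (presentation convention for percentages)
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric rounded with ties going up.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

.hcp_codes <- c("MD", "PH", "RN", "OT", "HP")
.non_hcp_codes <- c("CN", "LW")

#' Analysis configuration
#'
#' @param synonyms character vector of target-drug names (or a file path for
#'   [load_synonyms()]).
#' @param soc_map `data.table(pt, soc)` (or a file path for
#'   [load_soc_map()]); optional unless SOC-level runs are requested.
#' @param thresholds a [signal_thresholds()] set.
#' @param sensitivity_exclude character vector of drug names whose reports
#'   (any role) are removed in the sensitivity run. Defaults to the
#'   psychotropics commonly co-prescribed with the default target.
#' @param age_scheme stratum convention for subgroup runs (see
#'   [age_stratum()]).
#' @param top_k number of positive terms kept in ranked PT tables.
#' @param match_mode drug-name matching mode (see [select_primary_suspect()]).
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(synonyms = c("MIRTAZAPINE", "REMERON"),
                            soc_map = NULL,
                            thresholds = signal_thresholds(),
                            sensitivity_exclude = c("ESCITALOPRAM",
                                                    "SERTRALINE", "FLUOXETINE",
                                                    "VENLAFAXINE", "DULOXETINE",
                                                    "BUPROPION", "ARIPIPRAZOLE"),
                            age_scheme = "subgroup",
                            top_k = 50L,
                            match_mode = "whole_word") {
  if (is.character(synonyms) && length(synonyms) == 1L && file.exists(synonyms)) {
    synonyms <- load_synonyms(synonyms)
  }
  if (length(synonyms) == 0L) {
    stop("configuration error: synonym list is empty", call. = FALSE)
  }
  if (is.character(soc_map) && length(soc_map) == 1L) {
    soc_map <- load_soc_map(soc_map)
  }
  if (!is.numeric(top_k) || top_k < 1L) {
    stop("configuration error: top_k must be >= 1", call. = FALSE)
  }
  structure(list(synonyms = synonyms, soc_map = soc_map,
                 thresholds = thresholds,
                 sensitivity_exclude = sensitivity_exclude,
                 age_scheme = age_scheme, top_k = as.integer(top_k),
                 match_mode = match_mode),
            class = "analysis_config")
}

#' Baseline characteristics of a cohort
#'
#' Counts and percentages by sex, age stratum (baseline convention `<18`,
#' `18-65`, `>65`), reporter type (healthcare vs non-healthcare occupation
#' codes), top-10 reporter countries, and FDA receipt year. Percentages are
#' computed against the full cohort size (missing categories included) and
#' rounded half-up to one decimal.
#'
#' @param cohort_demo deduplicated DEMO rows of the cohort.
#' @return `data.table(section, category, n, pct)`.
#' @export
run_baseline <- function(cohort_demo) {
  demo <- data.table::as.data.table(cohort_demo)
  total <- nrow(demo)
  if (total == 0L) stop("run_baseline: empty cohort", call. = FALSE)

  count_section <- function(section, values, order_by_n = FALSE, top = NULL) {
    values[is.na(values)] <- "Missing"
    tab <- data.table::as.data.table(table(category = values))
    data.table::setnames(tab, c("category", "n"))
    tab[, "n" := as.integer(tab$n)]
    if (order_by_n) {
      tab <- tab[order(-tab$n, tab$category)]
      miss <- tab[tab$category == "Missing"]
      tab <- tab[tab$category != "Missing"]
      if (!is.null(top)) tab <- utils::head(tab, top)
      tab <- data.table::rbindlist(list(tab, miss))
    }
    tab[, "section" := section]
    tab
  }

  sex <- ifelse(demo$sex == "F", "Female",
                ifelse(demo$sex == "M", "Male", "Other"))
  age_years <- age_in_years(demo$age, demo$age_cod)
  strat <- age_stratum(age_years, "baseline")
  occ <- demo$occp_cod
  reporter <- ifelse(is.na(occ), NA_character_,
                     ifelse(occ %in% .hcp_codes, "Healthcare professional",
                            ifelse(occ %in% .non_hcp_codes,
                                   "Non-healthcare professional", "Other")))
  year <- format(demo$fda_dt, "%Y")

  out <- data.table::rbindlist(list(
    count_section("Gender", sex),
    count_section("Age", strat),
    count_section("Reporter", reporter),
    count_section("Top 10 Reported Countries", demo$reporter_country,
                  order_by_n = TRUE, top = 10L),
    count_section("Reporting year", year)
  ))
  out[, "pct" := round_half_up(100 * out$n / total, 1)]
  data.table::setcolorder(out, c("section", "category", "n", "pct"))
  out[]
}

.level_pairs <- function(reac, level, soc_map) {
  pairs <- unique(data.table::data.table(primaryid = reac$primaryid,
                                         term = reac$pt))
  if (level == "SOC") {
    if (is.null(soc_map)) {
      stop("SOC-level analysis requires a PT to SOC map", call. = FALSE)
    }
    mapped <- map_pt_to_soc(pairs$term, soc_map)
    keep <- mapped$soc != "UNMAPPED"
    n_dropped <- sum(!keep)
    if (n_dropped > 0L) {
      message(sprintf("SOC level: excluded %d (report, PT) pair(s) with unmapped terms",
                      n_dropped))
    }
    pairs <- unique(data.table::data.table(primaryid = pairs$primaryid[keep],
                                           term = mapped$soc[keep]))
  }
  pairs
}

#' Signal analysis at the PT or SOC level
#'
#' Builds per-term contingency tables for the cohort against all other
#' reports, fits the MGPS prior across every drug-term pair in the database
#' at the chosen level (unless a prior is supplied), and computes the full
#' metric set with the conjunctive verdict.
#'
#' @param demo deduplicated DEMO table for the whole database.
#' @param drug_rows DRUG table (used to fit the database-wide prior).
#' @param reac REAC table.
#' @param cohort_ids primaryids of the target-drug cohort.
#' @param level `"PT"` or `"SOC"`.
#' @param config an [analysis_config()].
#' @param prior optional pre-fitted `"gps_prior"` (fitted internally when
#'   `NULL`).
#' @return the [compute_signal_metrics()] table for all terms, with the
#'   fitted prior attached as attribute `"prior"`.
#' @export
run_level_analysis <- function(demo, drug_rows, reac, cohort_ids,
                               level = c("PT", "SOC"),
                               config = analysis_config(), prior = NULL) {
  level <- match.arg(level)
  demo <- data.table::as.data.table(demo)
  pairs <- .level_pairs(data.table::as.data.table(reac), level,
                        config$soc_map)
  in_cohort <- pairs$primaryid %in% cohort_ids
  n_cohort <- length(cohort_ids)
  n_background <- nrow(demo) - n_cohort
  tables <- build_contingency_tables(pairs[in_cohort], pairs[!in_cohort],
                                     n_cohort = n_cohort,
                                     n_background = n_background)
  if (is.null(prior)) {
    dp <- unique(data.table::data.table(
      primaryid = drug_rows$primaryid,
      drug = normalize_drugname(drug_rows$drugname)
    ))
    pe <- build_pair_expected(dp, pairs, n_reports = nrow(demo))
    prior <- gps_fit(pe$a, pe$e)
  }
  metrics <- compute_signal_metrics(tables, prior,
                                    thresholds = config$thresholds)
  data.table::setattr(metrics, "prior", prior)
  metrics
}

#' Top-K positive terms ranked by report count
#'
#' @param metrics a [compute_signal_metrics()] table.
#' @param k maximum rows kept.
#' @return the positive rows, ordered by descending count then term,
#'   truncated to `k`.
#' @export
top_positive <- function(metrics, k = 50L) {
  pos <- metrics[metrics$positive == TRUE]
  pos <- pos[order(-pos$a, pos$term)]
  utils::head(pos, k)
}

#' Sensitivity reanalysis excluding co-medicated reports
#'
#' Cohort reports listing any excluded drug in ANY role are removed; the
#' background is left unchanged; the level analysis is rerun on the reduced
#' cohort.
#'
#' @inheritParams run_level_analysis
#' @param exclude_synonyms drug names to exclude (defaults from `config`).
#' @return metrics table as in [run_level_analysis()], with attribute
#'   `"n_excluded"` (cohort reports removed).
#' @export
run_sensitivity <- function(demo, drug_rows, reac, cohort_ids,
                            level = "PT", config = analysis_config(),
                            exclude_synonyms = config$sensitivity_exclude) {
  drug_rows <- data.table::as.data.table(drug_rows)
  if (length(exclude_synonyms) == 0L) {
    stop("configuration error: sensitivity exclusion list is empty",
         call. = FALSE)
  }
  hit <- match_drugname(drug_rows$drugname, exclude_synonyms,
                        mode = config$match_mode)
  excluded_ids <- intersect(unique(drug_rows$primaryid[hit]), cohort_ids)
  keep <- !(data.table::as.data.table(demo)$primaryid %in% excluded_ids)
  demo_kept <- data.table::as.data.table(demo)[keep]
  reac_kept <- data.table::as.data.table(reac)[
    !(data.table::as.data.table(reac)$primaryid %in% excluded_ids)]
  out <- run_level_analysis(demo_kept, drug_rows, reac_kept,
                            setdiff(cohort_ids, excluded_ids),
                            level = level, config = config)
  data.table::setattr(out, "n_excluded", length(excluded_ids))
  out
}

#' Age-subgroup signal analyses
#'
#' Reports with missing (or non-convertible) age are excluded from all
#' strata; each stratum's cohort is analyzed against the full background.
#'
#' @inheritParams run_level_analysis
#' @return named list of metrics tables, one per stratum label (empty
#'   strata yield zero-row tables and a message).
#' @export
run_age_subgroups <- function(demo, drug_rows, reac, cohort_ids,
                              level = "PT", config = analysis_config()) {
  demo <- data.table::as.data.table(demo)
  age_years <- age_in_years(demo$age, demo$age_cod)
  strat <- age_stratum(age_years, config$age_scheme)
  labels <- if (config$age_scheme == "baseline") c("<18", "18-65", ">65")
            else c("<18", "18-64", ">=65")
  out <- list()
  for (lab in labels) {
    ids <- intersect(demo$primaryid[!is.na(strat) & strat == lab], cohort_ids)
    if (length(ids) == 0L) {
      message(sprintf("age subgroup '%s': empty stratum cohort", lab))
      out[[lab]] <- data.table::data.table()
      next
    }
    # stratum cohort vs full background: drop cohort reports outside the
    # stratum so they join neither side of the 2x2
    drop <- setdiff(cohort_ids, ids)
    demo_kept <- demo[!(demo$primaryid %in% drop)]
    reac_dt <- data.table::as.data.table(reac)
    reac_kept <- reac_dt[!(reac_dt$primaryid %in% drop)]
    out[[lab]] <- run_level_analysis(demo_kept, drug_rows, reac_kept, ids,
                                     level = level, config = config)
  }
  out
}

#' Full pipeline on in-memory tables
#'
#' Executes dedup -> cohort -> baseline -> SOC/PT signals -> sensitivity ->
#' age subgroups -> TTO/Weibull, returning every product plus the stage
#' counts of the flowchart.
#'
#' @param tables list with `demo`, `drug`, `reac`, `ther` typed tables.
#' @param config an [analysis_config()].
#' @param tto_ceiling_days implausibility ceiling for [compute_tto()].
#' @return list: `baseline`, `soc` (or NULL without a SOC map), `pt`,
#'   `pt_top` (ranked top-K), `sensitivity`, `subgroups`, `tto`
#'   (`summary`, `fit`, `exclusions`), `stage_counts`, `cohort_ids`.
#' @export
run_full_analysis <- function(tables, config = analysis_config(),
                              tto_ceiling_days = 7300) {
  dd <- deduplicate_reports(tables$demo)
  demo <- dd$survivors
  keep <- function(tab) tab[tab$primaryid %in% demo$primaryid]
  drug_rows <- keep(data.table::as.data.table(tables$drug))
  reac <- keep(data.table::as.data.table(tables$reac))
  ther <- keep(data.table::as.data.table(tables$ther))

  cohort_ids <- select_primary_suspect(drug_rows, config$synonyms,
                                       mode = config$match_mode)
  if (length(cohort_ids) == 0L) {
    stop("data error: no report matches the target-drug synonym list as primary suspect",
         call. = FALSE)
  }
  cohort_demo <- demo[demo$primaryid %in% cohort_ids]

  baseline <- run_baseline(cohort_demo)
  soc <- if (!is.null(config$soc_map)) {
    run_level_analysis(demo, drug_rows, reac, cohort_ids, "SOC", config)
  }
  pt <- run_level_analysis(demo, drug_rows, reac, cohort_ids, "PT", config)
  pt_top <- top_positive(pt, config$top_k)
  sens <- run_sensitivity(demo, drug_rows, reac, cohort_ids, "PT", config)
  subgroups <- run_age_subgroups(demo, drug_rows, reac, cohort_ids, "PT",
                                 config)

  suspect_seqs <- drug_rows[drug_rows$primaryid %in% cohort_ids &
                              !is.na(drug_rows$role_cod) &
                              drug_rows$role_cod == "PS" &
                              match_drugname(drug_rows$drugname,
                                             config$synonyms,
                                             mode = config$match_mode),
                            c("primaryid", "drug_seq"), with = FALSE]
  tto <- compute_tto(cohort_demo, ther, suspect_seqs = suspect_seqs,
                     ceiling_days = tto_ceiling_days)
  tto_summary <- if (nrow(tto$tto) > 0L) summarize_tto(tto$tto$tto_days)
  tto_fit <- if (nrow(tto$tto) >= 10L) fit_weibull(tto$tto$tto_days)

  list(
    baseline = baseline, soc = soc, pt = pt, pt_top = pt_top,
    sensitivity = sens, subgroups = subgroups,
    tto = list(records = tto$tto, exclusions = tto$exclusions,
               summary = tto_summary, fit = tto_fit),
    stage_counts = c(
      raw = nrow(tables$demo),
      deduplicated = nrow(demo),
      cohort = length(cohort_ids),
      sensitivity = length(cohort_ids) - attr(sens, "n_excluded"),
      tto_valid = nrow(tto$tto)
    ),
    cohort_ids = cohort_ids
  )
}
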