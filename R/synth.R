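# Synthetic FAERS-dialect data with planted ground truth.
#
# World model (documented in the methods vignette):
#  * every report gets exactly one primary-suspect (PS) drug, uniform over the
#    drug vocabulary, plus a Poisson number of extra drugs in roles SS/C/I;
#  * drug-event pairing is independent Bernoulli per (report, event) at
#    background_rate, multiplied by the planted rate ratio when the report
#    carries the planted drug -- so the true odds ratio of a planted pair is
#    (p r / (1 - p r)) / (p / (1 - p)), i.e. the configured ratio up to O(p);
#  * a small designated "filler" subset of the event vocabulary contributes
#    exactly one guaranteed PT per report, so every report has >= 1 reaction
#    row without disturbing non-filler odds ratios (planted signals may not
#    target filler terms);
#  * onset: START_DT uniform over the date window, EVENT_DT = START_DT plus a
#    Weibull(tto_shape, tto_scale) draw rounded to whole days, FDA_DT =
#    EVENT_DT plus a short reporting delay;
#  * duplicates: a configured fraction of cases receives one extra report
#    version with strictly later FDA_DT (or equal FDA_DT and higher
#    PRIMARYID), so the intended dedup survivor is unambiguous;
#  * date corruption truncates a configured fraction of EVENT_DT/START_DT to
#    month/year precision, blanks them, or pushes EVENT_DT before START_DT.

.check_fraction <- function(value, field, allow_one = FALSE) {
  hi_ok <- if (allow_one) value <= 1 else value < 1
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || !hi_ok) {
    stop(sprintf("configuration error: field '%s' must be a fraction in [0, %s)",
                 field, if (allow_one) "1]" else "1"), call. = FALSE)
  }
}

.check_pos <- function(value, field, integer = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0 ||
      (integer && value != round(value))) {
    stop(sprintf("configuration error: field '%s' must be a positive %s",
                 field, if (integer) "integer" else "real"), call. = FALSE)
  }
}

#' Build and validate a synthetic-data configuration
#'
#' Defaults state the emulated world once: report volume and vocabulary sizes
#' large enough for stable disproportionality estimates at desk scale, a
#' background reporting probability of 1e-3 per drug-event pair, onset
#' latencies from the early-failure Weibull regime (shape 0.49, scale 57.1
#' days), a 2004--2025 reporting window, and demographic mixes loosely
#' matching a large antidepressant cohort (~54% female; age mass in 18--65;
#' ~20% missing demographics).
#'
#' @param n_reports,n_drugs,n_events positive integers.
#' @param n_filler_events number of vocabulary terms reserved as guaranteed
#'   per-report filler (must be < `n_events`).
#' @param target_drug_name name of the drug under study (always in the
#'   vocabulary).
#' @param background_rate per-pair event probability in (0, 1).
#' @param planted_signals `data.frame(drug, event, rate_ratio)`; drugs/events
#'   must come from the configured vocabularies, events must be non-filler,
#'   ratios positive, and `background_rate * rate_ratio <= 1`.
#' @param duplicate_rate,partial_date_rate,missing_demo_rate fractions in
#'   `[0, 1)`.
#' @param tto_shape,tto_scale Weibull onset parameters (shape beta,
#'   scale alpha in days).
#' @param date_window length-2 `Date` (or coercible) start/end of the
#'   reporting window.
#' @param multi_suspect allow extra drugs to also carry the PS role.
#' @param extra_drug_mean Poisson mean of non-primary drug rows per report.
#' @param seed integer RNG seed; identical configs are byte-identical worlds.
#' @return list of class `"synth_config"` with the validated fields plus
#'   derived vocabularies `drug_vocab`, `event_vocab`, `filler_vocab`.
#' @export
synth_config <- function(n_reports = 20000L, n_drugs = 25L, n_events = 200L,
                         n_filler_events = 10L,
                         target_drug_name = "MIRTAZAPINE",
                         background_rate = 1e-3,
                         planted_signals = NULL,
                         duplicate_rate = 0.05,
                         partial_date_rate = 0.10,
                         missing_demo_rate = 0.20,
                         tto_shape = 0.49, tto_scale = 57.1,
                         date_window = as.Date(c("2004-01-01", "2025-03-31")),
                         multi_suspect = FALSE,
                         extra_drug_mean = 0.7,
                         seed = 1L) {
  .check_pos(n_reports, "n_reports", integer = TRUE)
  .check_pos(n_drugs, "n_drugs", integer = TRUE)
  .check_pos(n_events, "n_events", integer = TRUE)
  .check_pos(n_filler_events, "n_filler_events", integer = TRUE)
  if (n_filler_events >= n_events) {
    stop("configuration error: field 'n_filler_events' must be < n_events",
         call. = FALSE)
  }
  if (!is.character(target_drug_name) || !nzchar(target_drug_name)) {
    stop("configuration error: field 'target_drug_name' must be non-empty text",
         call. = FALSE)
  }
  .check_fraction(background_rate, "background_rate")
  if (background_rate <= 0) {
    stop("configuration error: field 'background_rate' must be positive",
         call. = FALSE)
  }
  .check_fraction(duplicate_rate, "duplicate_rate")
  .check_fraction(partial_date_rate, "partial_date_rate")
  .check_fraction(missing_demo_rate, "missing_demo_rate")
  .check_pos(tto_shape, "tto_shape")
  .check_pos(tto_scale, "tto_scale")
  .check_pos(extra_drug_mean + 1, "extra_drug_mean")  # >= 0 allowed
  date_window <- as.Date(date_window)
  if (length(date_window) != 2L || anyNA(date_window) ||
      date_window[1L] >= date_window[2L]) {
    stop("configuration error: field 'date_window' must be two ordered dates",
         call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("configuration error: field 'seed' must be an integer", call. = FALSE)
  }

  drug_vocab <- c(toupper(target_drug_name),
                  sprintf("DRUG_%03d", seq_len(n_drugs - 1L)))
  event_vocab <- sprintf("EVENT_%04d", seq_len(n_events))
  filler_vocab <- utils::tail(event_vocab, n_filler_events)

  if (!is.null(planted_signals)) {
    ps <- data.table::as.data.table(planted_signals)
    if (!all(c("drug", "event", "rate_ratio") %in% names(ps))) {
      stop("configuration error: field 'planted_signals' needs columns drug, event, rate_ratio",
           call. = FALSE)
    }
    ps[, "drug" := toupper(ps$drug)]
    if (!all(ps$drug %in% drug_vocab)) {
      stop("configuration error: field 'planted_signals' names a drug outside the vocabulary",
           call. = FALSE)
    }
    if (!all(ps$event %in% setdiff(event_vocab, filler_vocab))) {
      stop("configuration error: field 'planted_signals' must target non-filler vocabulary events",
           call. = FALSE)
    }
    if (any(ps$rate_ratio <= 0) ||
        any(background_rate * ps$rate_ratio > 1)) {
      stop("configuration error: field 'planted_signals' rate_ratio must be positive with background_rate * rate_ratio <= 1",
           call. = FALSE)
    }
    if (anyDuplicated(ps$event)) {
      stop("configuration error: field 'planted_signals' may plant at most one drug per event",
           call. = FALSE)
    }
    planted_signals <- ps
  } else {
    planted_signals <- data.table::data.table(drug = character(),
                                              event = character(),
                                              rate_ratio = numeric())
  }

  structure(list(
    n_reports = as.integer(n_reports), n_drugs = as.integer(n_drugs),
    n_events = as.integer(n_events),
    n_filler_events = as.integer(n_filler_events),
    target_drug_name = toupper(target_drug_name),
    background_rate = background_rate, planted_signals = planted_signals,
    duplicate_rate = duplicate_rate, partial_date_rate = partial_date_rate,
    missing_demo_rate = missing_demo_rate,
    tto_shape = tto_shape, tto_scale = tto_scale,
    date_window = date_window, multi_suspect = multi_suspect,
    extra_drug_mean = extra_drug_mean, seed = as.integer(seed),
    drug_vocab = drug_vocab, event_vocab = event_vocab,
    filler_vocab = filler_vocab
  ), class = "synth_config")
}

# demographic mixes, loosely shaped like a large antidepressant cohort
.demo_mixes <- list(
  sex = c(F = 0.62, M = 0.38),
  age_stratum = c("<18" = 0.035, "18-65" = 0.614, ">65" = 0.351),
  occp = c(MD = 0.30, PH = 0.12, OT = 0.22, RN = 0.08, CN = 0.26, LW = 0.02),
  country = c("UNITED KINGDOM" = 0.27, "UNITED STATES" = 0.19,
              "FRANCE" = 0.10, "GERMANY" = 0.09, "ITALY" = 0.05,
              "JAPAN" = 0.04, "SWEDEN" = 0.033, "CANADA" = 0.03,
              "SPAIN" = 0.022, "NETHERLANDS" = 0.016, "OTHER" = 0.149)
)

#' Generate a synthetic FAERS-dialect dataset with ground truth
#'
#' @param config a [synth_config()].
#' @return list with typed tables `demo`, `drug`, `reac`, `ther` (same shapes
#'   as [read_faers_table()] output) and `manifest`, a ground-truth list:
#'   `planted` (drug, event, rate_ratio), `duplicate_groups` (caseid,
#'   members, survivor), `n_injected_duplicates`, `corrupted`
#'   (primaryid, field, kind), `tto` (primaryid, true onset days, valid flag),
#'   `tto_shape`, `tto_scale`, `seed`.
#' @export
generate_faers_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_reports

  primaryid <- seq_len(n) * 10L
  caseid <- seq_len(n)

  ## --- drugs -----------------------------------------------------------
  ps_drug <- sample(config$drug_vocab, n, replace = TRUE)
  n_extra <- stats::rpois(n, config$extra_drug_mean)
  extra_roles_pool <- if (config$multi_suspect) c("PS", "SS", "C", "I")
                      else c("SS", "C", "I")
  total_extra <- sum(n_extra)
  extra_idx <- rep.int(seq_len(n), n_extra)
  extra_drug <- sample(config$drug_vocab, total_extra, replace = TRUE)
  extra_role <- sample(extra_roles_pool, total_extra, replace = TRUE)
  drug <- data.table::data.table(
    primaryid = c(primaryid, primaryid[extra_idx]),
    drug_seq = c(rep(1L, n), unlist(lapply(n_extra[n_extra > 0L], seq_len),
                                    use.names = FALSE) + 1L),
    role_cod = c(rep("PS", n), extra_role),
    drugname = c(ps_drug, extra_drug)
  )
  data.table::setorderv(drug, c("primaryid", "drug_seq"))

  ## --- reactions -------------------------------------------------------
  # report -> set of drugs carried (any role), for planted-rate lookups
  planted <- config$planted_signals
  carrier <- list()
  for (dname in unique(planted$drug)) {
    has <- rep(FALSE, n)
    has[match(unique(drug$primaryid[drug$drugname == dname]), primaryid)] <- TRUE
    carrier[[dname]] <- has
  }
  reac_parts <- vector("list", config$n_events + 1L)
  for (j in seq_len(config$n_events)) {
    ev <- config$event_vocab[j]
    p <- rep(config$background_rate, n)
    k <- match(ev, planted$event)
    if (!is.na(k)) {
      idx <- carrier[[planted$drug[k]]]
      p[idx] <- pmin(p[idx] * planted$rate_ratio[k], 1)
    }
    hit <- stats::runif(n) < p
    if (any(hit)) {
      reac_parts[[j]] <- data.table::data.table(primaryid = primaryid[hit],
                                                pt = ev)
    }
  }
  filler <- sample(config$filler_vocab, n, replace = TRUE)
  reac_parts[[config$n_events + 1L]] <-
    data.table::data.table(primaryid = primaryid, pt = filler)
  reac <- unique(data.table::rbindlist(reac_parts))
  data.table::setorderv(reac, c("primaryid", "pt"))

  ## --- dates and onset -------------------------------------------------
  window_days <- as.integer(config$date_window[2L] - config$date_window[1L])
  start_dt <- config$date_window[1L] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L
  tto_true <- round(stats::rweibull(n, shape = config$tto_shape,
                                    scale = config$tto_scale))
  event_dt <- start_dt + tto_true
  fda_dt <- event_dt + sample.int(91L, n, replace = TRUE) - 1L

  ## --- demographics ----------------------------------------------------
  sex <- sample(names(.demo_mixes$sex), n, replace = TRUE,
                prob = .demo_mixes$sex)
  stratum <- sample(names(.demo_mixes$age_stratum), n, replace = TRUE,
                    prob = .demo_mixes$age_stratum)
  age <- numeric(n)
  age[stratum == "<18"] <- sample(2:17, sum(stratum == "<18"), replace = TRUE)
  age[stratum == "18-65"] <- sample(18:65, sum(stratum == "18-65"),
                                    replace = TRUE)
  age[stratum == ">65"] <- sample(66:95, sum(stratum == ">65"), replace = TRUE)
  occp <- sample(names(.demo_mixes$occp), n, replace = TRUE,
                 prob = .demo_mixes$occp)
  country <- sample(names(.demo_mixes$country), n, replace = TRUE,
                    prob = .demo_mixes$country)
  miss <- function(x) {
    x[stats::runif(n) < config$missing_demo_rate] <- NA
    x
  }
  sex <- miss(sex); age <- miss(age); occp <- miss(occp)
  country <- miss(country)
  age_cod <- ifelse(is.na(age), NA_character_, "YR")

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = format_faers_date(event_dt),
    age = age, age_cod = age_cod, sex = sex, occp_cod = occp,
    reporter_country = country
  )
  ther <- data.table::data.table(
    primaryid = primaryid, dsg_drug_seq = 1L,
    start_dt = format_faers_date(start_dt)
  )

  ## --- date corruption (before duplication: copies inherit corruption) --
  corrupted <- corrupt_dates(demo, ther, config$partial_date_rate)
  demo <- corrupted$demo
  ther <- corrupted$ther

  ## --- duplicate injection ---------------------------------------------
  n_dup <- as.integer(round(config$duplicate_rate * n))
  if (n_dup > 0L) {
    dup_of <- sort(sample.int(n, n_dup))
    delay <- sample.int(181L, n_dup, replace = TRUE) - 1L  # 0..180 days
    dup_demo <- demo[dup_of]
    dup_demo[, "primaryid" := dup_demo$primaryid + 1L]
    dup_demo[, "fda_dt" := dup_demo$fda_dt + delay]
    id_map <- data.table::data.table(primaryid = primaryid[dup_of],
                                     new_id = primaryid[dup_of] + 1L)
    clone <- function(tab) {
      cl <- merge(tab, id_map, by = "primaryid")
      cl[, "primaryid" := cl$new_id]
      cl[, "new_id" := NULL]
      cl
    }
    demo <- data.table::rbindlist(list(demo, dup_demo))
    drug <- data.table::rbindlist(list(drug, clone(drug)))
    reac <- data.table::rbindlist(list(reac, clone(reac)))
    ther <- data.table::rbindlist(list(ther, clone(ther)))
    duplicate_groups <- data.table::data.table(
      caseid = caseid[dup_of],
      members = paste(primaryid[dup_of], primaryid[dup_of] + 1L, sep = "|"),
      survivor = primaryid[dup_of] + 1L
    )
  } else {
    duplicate_groups <- data.table::data.table(caseid = integer(),
                                               members = character(),
                                               survivor = integer())
  }
  data.table::setorderv(demo, "primaryid")
  data.table::setorderv(drug, c("primaryid", "drug_seq"))
  data.table::setorderv(reac, c("primaryid", "pt"))
  data.table::setorderv(ther, c("primaryid", "dsg_drug_seq"))

  manifest <- list(
    planted = planted,
    duplicate_groups = duplicate_groups,
    n_injected_duplicates = n_dup,
    corrupted = corrupted$log,
    tto = data.table::data.table(primaryid = primaryid, tto_days = tto_true),
    tto_shape = config$tto_shape, tto_scale = config$tto_scale,
    seed = config$seed,
    target_drug_name = config$target_drug_name
  )
  list(demo = demo, drug = drug, reac = reac, ther = ther,
       manifest = manifest)
}

#' Corrupt a fraction of EVENT_DT / START_DT values
#'
#' Each EVENT_DT and each START_DT is independently selected with probability
#' `rate`; a selected value is truncated to `YYYYMM` or `YYYY`, blanked, or
#' (EVENT_DT only) moved to precede the report's START_DT. The returned log
#' records which values were touched and how, so downstream exclusion logic
#' can be verified against ground truth.
#'
#' @param demo,ther typed tables whose `event_dt` / `start_dt` columns are
#'   8-digit date strings.
#' @param rate fraction in `[0, 1)`.
#' @return list `demo`, `ther` (modified copies) and
#'   `log`: `data.table(primaryid, field, kind)` with kind in
#'   `truncate_month`, `truncate_year`, `blank`, `event_before_start`.
#' @export
corrupt_dates <- function(demo, ther, rate) {
  .check_fraction(rate, "partial_date_rate")
  demo <- data.table::copy(data.table::as.data.table(demo))
  ther <- data.table::copy(data.table::as.data.table(ther))
  logs <- list()

  if (rate > 0) {
    kinds_e <- c("truncate_month", "truncate_year", "blank",
                 "event_before_start")
    pick_e <- which(stats::runif(nrow(demo)) < rate & nzchar(demo$event_dt) &
                    !is.na(demo$event_dt))
    if (length(pick_e) > 0L) {
      kind_e <- sample(kinds_e, length(pick_e), replace = TRUE,
                       prob = c(0.35, 0.25, 0.15, 0.25))
      v <- demo$event_dt[pick_e]
      v[kind_e == "truncate_month"] <- substr(v[kind_e == "truncate_month"], 1L, 6L)
      v[kind_e == "truncate_year"] <- substr(v[kind_e == "truncate_year"], 1L, 4L)
      v[kind_e == "blank"] <- ""
      before <- kind_e == "event_before_start"
      if (any(before)) {
        st <- ther$start_dt[match(demo$primaryid[pick_e][before],
                                  ther$primaryid)]
        st_date <- partial_date_as_date(parse_faers_date(st))
        shift <- sample.int(60L, sum(before), replace = TRUE)
        moved <- format_faers_date(st_date - shift)
        # if START_DT itself is unusable, fall back to blanking
        v[before] <- ifelse(nzchar(moved), moved, "")
        kind_e[before][!nzchar(moved)] <- "blank"
      }
      demo[pick_e, "event_dt" := v]
      logs[[1L]] <- data.table::data.table(primaryid = demo$primaryid[pick_e],
                                           field = "event_dt", kind = kind_e)
    }
    kinds_s <- c("truncate_month", "truncate_year", "blank")
    pick_s <- which(stats::runif(nrow(ther)) < rate & nzchar(ther$start_dt) &
                    !is.na(ther$start_dt))
    if (length(pick_s) > 0L) {
      kind_s <- sample(kinds_s, length(pick_s), replace = TRUE,
                       prob = c(0.45, 0.3, 0.25))
      v <- ther$start_dt[pick_s]
      v[kind_s == "truncate_month"] <- substr(v[kind_s == "truncate_month"], 1L, 6L)
      v[kind_s == "truncate_year"] <- substr(v[kind_s == "truncate_year"], 1L, 4L)
      v[kind_s == "blank"] <- ""
      ther[pick_s, "start_dt" := v]
      logs[[2L]] <- data.table::data.table(primaryid = ther$primaryid[pick_s],
                                           field = "start_dt", kind = kind_s)
    }
  }
  log <- if (length(logs) > 0L) data.table::rbindlist(logs)
         else data.table::data.table(primaryid = integer(), field = character(),
                                     kind = character())
  list(demo = demo, ther = ther, log = log)
}

#' Intended post-deduplication survivors for a synthetic dataset
#'
#' @param dataset output of [generate_faers_dataset()].
#' @return sorted integer vector of the PRIMARYIDs the FDA rules must retain.
#' @export
manifest_survivors <- function(dataset) {
  all_ids <- dataset$demo$primaryid
  groups <- dataset$manifest$duplicate_groups
  losers <- setdiff(
    as.integer(unlist(strsplit(groups$members, "|", fixed = TRUE))),
    groups$survivor
  )
  sort(setdiff(all_ids, losers))
}

#' Write a synthetic dataset (tables + manifest) to a directory
#'
#' Files: `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt` in the `"$"`
#' dialect, plus `manifest.txt` as a flat key-value file.
#'
#' @param dataset output of [generate_faers_dataset()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_faers_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_faers_table(dataset$demo, file.path(dir, "DEMO.txt"), "demo"),
    write_faers_table(dataset$drug, file.path(dir, "DRUG.txt"), "drug"),
    write_faers_table(dataset$reac, file.path(dir, "REAC.txt"), "reac"),
    write_faers_table(dataset$ther, file.path(dir, "THER.txt"), "ther"),
    write_manifest(dataset$manifest, file.path(dir, "manifest.txt"))
  )
  invisible(paths)
}

#' Write / read the ground-truth manifest as a flat key-value text file
#'
#' @param manifest manifest list from [generate_faers_dataset()].
#' @param path file path.
#' @return `path` invisibly (writer); manifest list (reader).
#' @export
write_manifest <- function(manifest, path) {
  lines <- c(
    sprintf("seed=%d", manifest$seed),
    sprintf("target_drug_name=%s", manifest$target_drug_name),
    sprintf("tto_shape=%.10g", manifest$tto_shape),
    sprintf("tto_scale=%.10g", manifest$tto_scale),
    sprintf("n_injected_duplicates=%d", manifest$n_injected_duplicates)
  )
  p <- manifest$planted
  if (nrow(p) > 0L) {
    lines <- c(lines, sprintf("planted.%d=%s|%s|%.10g", seq_len(nrow(p)),
                              p$drug, p$event, p$rate_ratio))
  }
  g <- manifest$duplicate_groups
  if (nrow(g) > 0L) {
    lines <- c(lines, sprintf("dup.%d=%d|%s|%d", seq_len(nrow(g)),
                              g$caseid, g$members, g$survivor))
  }
  cr <- manifest$corrupted
  if (nrow(cr) > 0L) {
    lines <- c(lines, sprintf("corrupt.%d=%d|%s|%s", seq_len(nrow(cr)),
                              cr$primaryid, cr$field, cr$kind))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1L))
  split3 <- function(v) strsplit(v, "|", fixed = TRUE)

  planted_v <- vals[startsWith(keys, "planted.")]
  planted <- if (length(planted_v) > 0L) {
    parts <- split3(planted_v)
    data.table::data.table(
      drug = vapply(parts, `[[`, character(1L), 1L),
      event = vapply(parts, `[[`, character(1L), 2L),
      rate_ratio = as.numeric(vapply(parts, `[[`, character(1L), 3L))
    )
  } else {
    data.table::data.table(drug = character(), event = character(),
                           rate_ratio = numeric())
  }
  dup_v <- vals[startsWith(keys, "dup.")]
  dup <- if (length(dup_v) > 0L) {
    parts <- split3(dup_v)
    data.table::data.table(
      caseid = as.integer(vapply(parts, `[[`, character(1L), 1L)),
      members = vapply(parts, function(x)
        paste(x[-c(1L, length(x))], collapse = "|"), character(1L)),
      survivor = as.integer(vapply(parts, function(x) x[[length(x)]],
                                   character(1L)))
    )
  } else {
    data.table::data.table(caseid = integer(), members = character(),
                           survivor = integer())
  }
  cr_v <- vals[startsWith(keys, "corrupt.")]
  corrupted <- if (length(cr_v) > 0L) {
    parts <- split3(cr_v)
    data.table::data.table(
      primaryid = as.integer(vapply(parts, `[[`, character(1L), 1L)),
      field = vapply(parts, `[[`, character(1L), 2L),
      kind = vapply(parts, `[[`, character(1L), 3L)
    )
  } else {
    data.table::data.table(primaryid = integer(), field = character(),
                           kind = character())
  }
  list(
    planted = planted,
    duplicate_groups = dup,
    n_injected_duplicates =
      as.integer(vals[keys == "n_injected_duplicates"]),
    corrupted = corrupted,
    tto_shape = as.numeric(vals[keys == "tto_shape"]),
    tto_scale = as.numeric(vals[keys == "tto_scale"]),
    seed = as.integer(vals[keys == "seed"]),
    target_drug_name = vals[keys == "target_drug_name"]
  )
}
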