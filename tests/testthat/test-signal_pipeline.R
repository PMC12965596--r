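# signal_pipeline: baseline characteristics, level analyses, sensitivity,
# age subgroups

test_that("run_baseline computes percentages against the full cohort", {
  demo <- make_demo(1:10, 1:10, rep("2020-03-01", 10),
                    sex = c(rep("M", 10)))
  b <- run_baseline(demo)
  male <- b[b$section == "Gender" & b$category == "Male"]
  expect_equal(male$n, 10L)
  expect_equal(male$pct, 100.0)
  expect_false("Female" %in% b$category[b$section == "Gender"])
  expect_error(run_baseline(demo[0]), "empty cohort")

  # published-style arithmetic: 9711 female of 17953 -> 54.1%
  expect_equal(round_half_up(100 * 9711 / 17953, 1), 54.1)
  expect_equal(round_half_up(100 * 8681 / 17953, 1), 48.4)
})

test_that("baseline sections include missing categories and top-10 countries", {
  ds <- generate_faers_dataset(small_world(seed = 15L, n_reports = 4000L))
  dd <- deduplicate_reports(ds$demo)
  b <- run_baseline(dd$survivors)
  expect_setequal(unique(b$section),
                  c("Gender", "Age", "Reporter", "Top 10 Reported Countries",
                    "Reporting year"))
  countries <- b[b$section == "Top 10 Reported Countries"]
  expect_lte(sum(countries$category != "Missing"), 10L)
  # percentages computed against full cohort size including missing
  gender <- b[b$section == "Gender"]
  expect_equal(sum(gender$n), nrow(dd$survivors))
  expect_true("Missing" %in% gender$category)
})

test_that("configured sex mix is recovered within 3 binomial SDs", {
  ds <- generate_faers_dataset(small_world(seed = 16L, n_reports = 20000L,
                                           missing_demo_rate = 0))
  frac_f <- mean(ds$demo$sex == "F")
  expect_lt(abs(frac_f - 0.62), 3 * sqrt(0.62 * 0.38 / nrow(ds$demo)))
})

test_that("planted signals are exactly the positives at the PT level", {
  cfg <- small_world(seed = 18L, n_reports = 30000L)
  ds <- generate_faers_dataset(cfg)
  dd <- deduplicate_reports(ds$demo)
  cohort <- select_primary_suspect(ds$drug[ds$drug$primaryid %in%
                                             dd$survivors$primaryid],
                                   "MIRTAZAPINE")
  pt <- run_level_analysis(dd$survivors, ds$drug, ds$reac, cohort, "PT",
                           analysis_config(synonyms = "MIRTAZAPINE"))
  expect_setequal(pt$term[pt$positive], cfg$planted_signals$event)
  # top-K truncation: fewer positives than K -> all of them, ranked by count
  top <- top_positive(pt, 50L)
  expect_equal(nrow(top), 3L)
  expect_equal(top$a, sort(top$a, decreasing = TRUE))
  expect_equal(nrow(top_positive(pt, 2L)), 2L)
})

test_that("SOC aggregation counts a report once per organ class", {
  # one cohort report with two PTs in the same SOC
  demo <- make_demo(1:30, 1:30, rep("2020-01-01", 30))
  reac <- data.table::data.table(
    primaryid = c(1L, 1L, 2L, 3:20),
    pt = c("PT_A", "PT_B", "PT_A", rep("PT_C", 18))
  )
  soc_map <- data.table::data.table(pt = c("PT_A", "PT_B", "PT_C"),
                                    soc = c("SOC_1", "SOC_1", "SOC_2"))
  drug <- make_drug(1:30, rep("PS", 30),
                    c(rep("MIRTAZAPINE", 2), rep("OTHER", 28)))
  cfg <- analysis_config(synonyms = "MIRTAZAPINE", soc_map = soc_map)
  cohort <- select_primary_suspect(drug, "MIRTAZAPINE")
  soc <- suppressMessages(
    run_level_analysis(demo, drug, reac, cohort, "SOC", cfg,
                       prior = weak_prior()))
  s1 <- soc[soc$term == "SOC_1"]
  expect_equal(s1$a, 2L)  # report 1 counted once despite two PTs
  expect_equal(s1$a + s1$b, 2L)
  # unmapped PTs are excluded with a message
  reac2 <- rbind(reac, data.table::data.table(primaryid = 21L, pt = "PT_X"))
  expect_message(
    suppressWarnings(run_level_analysis(demo, drug, reac2, cohort, "SOC", cfg,
                                        prior = weak_prior())),
    "unmapped")
  expect_error(
    run_level_analysis(demo, drug, reac, cohort, "SOC",
                       analysis_config(synonyms = "MIRTAZAPINE"),
                       prior = weak_prior()),
    "SOC map")
})

test_that("sensitivity removes co-medicated cohort reports in any role", {
  demo <- make_demo(1:40, 1:40, rep("2020-01-01", 40))
  reac <- data.table::data.table(primaryid = rep(1:40, 2),
                                 pt = c(rep("E1", 40), rep("E2", 40)))
  # cohort reports 1..4; report 2 lists sertraline as concomitant
  drug <- rbind(
    make_drug(1:4, rep("PS", 4), rep("MIRTAZAPINE", 4)),
    make_drug(2L, "C", "SERTRALINE", drug_seq = 2L),
    make_drug(5:40, rep("PS", 36), rep("OTHER", 36))
  )
  cfg <- analysis_config(synonyms = "MIRTAZAPINE")
  cohort <- select_primary_suspect(drug, "MIRTAZAPINE")
  sens <- run_sensitivity(demo, drug, reac, cohort, "PT", cfg)
  expect_equal(attr(sens, "n_excluded"), 1L)
  expect_equal(unique(sens$a + sens$b), 3L)       # cohort shrank
  expect_equal(unique(sens$c + sens$d), 36L)      # background untouched
  # no excluded drug present -> identical to the primary analysis
  drug2 <- drug[drug$drugname != "SERTRALINE"]
  sens2 <- run_sensitivity(demo, drug2, reac, cohort, "PT", cfg,
                           exclude_synonyms = "SERTRALINE")
  prim <- run_level_analysis(demo, drug2, reac, cohort, "PT", cfg)
  expect_equal(as.data.frame(sens2), as.data.frame(prim), ignore_attr = TRUE)
  expect_error(run_sensitivity(demo, drug, reac, cohort, "PT", cfg,
                               exclude_synonyms = character()),
               "exclusion list")
})

test_that("sensitivity keeps planted signals that avoid excluded drugs", {
  cfg <- small_world(seed = 19L, n_reports = 30000L)
  ds <- generate_faers_dataset(cfg)
  dd <- deduplicate_reports(ds$demo)
  acfg <- analysis_config(synonyms = "MIRTAZAPINE",
                          sensitivity_exclude = c("DRUG_001", "DRUG_002"))
  cohort <- select_primary_suspect(ds$drug, "MIRTAZAPINE")
  cohort <- intersect(cohort, dd$survivors$primaryid)
  sens <- run_sensitivity(dd$survivors, ds$drug, ds$reac, cohort, "PT", acfg)
  expect_setequal(sens$term[sens$positive], cfg$planted_signals$event)
})

test_that("age subgroups partition non-missing ages; missing joins no stratum", {
  demo <- make_demo(1:6, 1:6, rep("2020-01-01", 6),
                    age = c(10, 40, 70, 65, NA, 17))
  reac <- data.table::data.table(primaryid = 1:6, pt = "E1")
  drug <- make_drug(1:6, rep("PS", 6), rep("MIRTAZAPINE", 6))
  cfg <- analysis_config(synonyms = "MIRTAZAPINE")
  cohort <- select_primary_suspect(drug, "MIRTAZAPINE")
  subs <- suppressMessages(
    run_age_subgroups(demo, drug, reac, cohort, "PT", cfg))
  expect_named(subs, c("<18", "18-64", ">=65"))
  sizes <- vapply(subs, function(t) if (nrow(t)) t$a[1] + t$b[1] else 0L,
                  numeric(1))
  expect_equal(unname(sizes), c(2, 1, 2))  # ages 10,17 | 40 | 70,65
  # missing-age report is in no stratum but still in the baseline Missing row
  b <- run_baseline(demo)
  expect_equal(b[b$section == "Age" & b$category == "Missing"]$n, 1L)
  # strata are disjoint subsets of the cohort
  total <- sum(sizes)
  expect_equal(total, 5)
})

test_that("full pipeline is deterministic and stage counts are coherent", {
  cfg <- small_world(seed = 20L, n_reports = 5000L)
  ds <- generate_faers_dataset(cfg)
  acfg <- analysis_config(synonyms = "MIRTAZAPINE",
                          soc_map = make_soc_map(cfg$event_vocab))
  r1 <- suppressMessages(run_full_analysis(ds, acfg))
  r2 <- suppressMessages(run_full_analysis(ds, acfg))
  expect_equal(r1$pt, r2$pt, ignore_attr = TRUE)
  expect_equal(r1$baseline, r2$baseline)
  sc <- r1$stage_counts
  expect_equal(sc[["raw"]], nrow(ds$demo))
  expect_equal(sc[["deduplicated"]],
               data.table::uniqueN(ds$demo$caseid))
  expect_lte(sc[["sensitivity"]], sc[["cohort"]])
  expect_lte(sc[["tto_valid"]], sc[["cohort"]])
  expect_false(is.null(r1$soc))
})
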