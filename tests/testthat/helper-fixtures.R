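# Shared fixture builders. Everything is generated in code; nothing binary.

# tiny DEMO-style table with full control over the dedup-relevant keys
make_demo <- function(primaryid, caseid, fda_dt,
                      event_dt = rep("", length(primaryid)),
                      age = rep(NA_real_, length(primaryid)),
                      age_cod = rep("YR", length(primaryid)),
                      sex = rep(NA_character_, length(primaryid)),
                      occp_cod = rep(NA_character_, length(primaryid)),
                      reporter_country = rep(NA_character_, length(primaryid))) {
  data.table::data.table(
    primaryid = as.integer(primaryid), caseid = as.integer(caseid),
    fda_dt = as.Date(fda_dt), event_dt = event_dt,
    age = age, age_cod = age_cod, sex = sex, occp_cod = occp_cod,
    reporter_country = reporter_country
  )
}

make_drug <- function(primaryid, role_cod, drugname,
                      drug_seq = seq_along(primaryid)) {
  data.table::data.table(primaryid = as.integer(primaryid),
                         drug_seq = as.integer(drug_seq),
                         role_cod = role_cod, drugname = drugname)
}

# PT -> SOC map covering a synthetic event vocabulary: events are assigned
# round-robin to n_soc organ classes
make_soc_map <- function(event_vocab, n_soc = 10L) {
  data.table::data.table(
    pt = event_vocab,
    soc = sprintf("SOC_%02d", (seq_along(event_vocab) - 1L) %% n_soc + 1L)
  )
}

# default small planted-signal world used across tests
small_world <- function(seed = 1L, n_reports = 20000L, rate_ratio = 8,
                        extra_drug_mean = 0.7, ...) {
  planted <- data.frame(
    drug = "MIRTAZAPINE",
    event = c("EVENT_0001", "EVENT_0050", "EVENT_0100"),
    rate_ratio = rate_ratio
  )
  synth_config(n_reports = n_reports, n_drugs = 10L, n_events = 120L,
               background_rate = 2e-3, planted_signals = planted,
               extra_drug_mean = extra_drug_mean, seed = seed, ...)
}

# weakly informative prior used where the EBGM machinery is exercised
# without fitting
weak_prior <- function() gps_prior(0.2, 0.1, 2, 2, 1 / 3)
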