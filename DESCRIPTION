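Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("FAERS", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A reusable pharmacovigilance pipeline for FAERS-style spontaneous
    adverse event report databases: quarterly ASCII table ingestion, FDA-rule
    deduplication, primary-suspect cohort construction, four disproportionality
    algorithms (reporting odds ratio, proportional reporting ratio, BCPNN
    information component, and the multi-item gamma Poisson shrinker) combined
    through a conjunctive signal gate, sensitivity and age-subgroup reanalysis,
    and Weibull time-to-onset failure modeling. Includes a synthetic FAERS
    generator with planted ground truth so the whole pipeline is testable
    without access to the external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
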