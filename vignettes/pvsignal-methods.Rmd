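---
title: "Methods: disproportionality signal detection for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS accumulate
millions of drug–event reports with no denominator: there is no count of
patients exposed, only of reports received. Safety screening therefore asks
a relative question — is event *Y* reported disproportionately often with
drug *X*, compared with the reporting of *Y* across all other drugs? The
whole analysis reduces to, per event term, a 2×2 contingency table:

|              | target term | all other terms |
|--------------|------------:|----------------:|
| target drug  | a           | b               |
| other drugs  | c           | d               |

with `N = a + b + c + d`. The counting unit is the **distinct report**: a
report mentioning the same preferred term (PT) twice counts once, and at the
system-organ-class (SOC) level a report contributes once per SOC regardless
of how many of its PTs map there.

`pvsignal` implements that screening pipeline end to end: FAERS-dialect
ingestion, case deduplication, primary-suspect cohort construction, four
disproportionality statistics behind a conjunctive gate, sensitivity and
age-subgroup reanalysis, and Weibull time-to-onset modeling — together with
a synthetic report generator with planted ground truth, so every stage is
testable without the external database.

## Data model and cleaning

**Deduplication.** Reporting systems carry multiple versions of one case.
Per `CASEID`, the report with the most recent `FDA_DT` is retained; ties are
broken by the highest `PRIMARYID`. Both rules collapse to one lexicographic
sort key, which makes `deduplicate_reports()` total, order-invariant, and
idempotent — properties the test suite asserts directly, and which the
synthetic generator's duplicate-injection manifest verifies exactly.

**Cohort.** A report joins the target-drug cohort iff at least one DRUG row
has role code `PS` (primary suspect) *and* a drug name matching the synonym
list. Verbatim FAERS drug names embed doses and brand wrappers
(`"Remeron (mirtazapine) 15mg tab"`), so the default match is
case-insensitive whole-word matching on punctuation-stripped names; a
substring mode is available by flag. The matching procedure is a documented
package choice: source analyses rarely state theirs.

**Dates.** FAERS dates appear at day (`YYYYMMDD`), month (`YYYYMM`) and year
(`YYYY`) precision. `parse_faers_date()` is total: impossible calendar
combinations and malformed strings parse to missing, never to an error.

**PT→SOC map.** MedDRA is licensed and is never bundled. SOC-level analyses
require a user-supplied two-column file; each PT is assumed to carry its
primary SOC only (no multi-axial expansion). Unmapped PTs go to an explicit
`UNMAPPED` bucket and are excluded from SOC tables with a logged count.

**Age.** Only `YR` and `DEC` age units are converted to years; other unit
codes (months, weeks, days) are carried but excluded from stratification,
since only adult/elderly strata are consumed downstream. Two labeled stratum
conventions exist because descriptive tables and subgroup analyses in this
field use slightly different boundaries: `baseline` = `<18`, `18–65`
(inclusive), `>65`; `subgroup` = `<18`, `18–64`, `≥65` (age exactly 65 falls
in the oldest stratum).

## The four algorithms

With `E = (a+b)(a+c)/N` the count expected under independence:

* **ROR** (reporting odds ratio): `ad/bc`, with the log-normal 95% CI
  `exp(log ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`. Any zero cell renders the
  statistic undefined-with-reason; no Haldane continuity correction is
  applied by default, because manufacturing a finite odds ratio for `a = 0`
  terms silently creates signals.
* **PRR** (proportional reporting ratio): `(a/(a+b)) / (c/(c+d))`, paired
  with the Pearson χ² on the 2×2. χ² uses the Yates continuity correction
  by default (flag-switchable), in the clamped form
  `N·max(|ad−bc|−N/2, 0)² / ((a+b)(c+d)(a+c)(b+d))`, which is exactly zero
  at exact independence.
* **BCPNN information component**:
  `IC = log2((a+0.5)/(E+0.5))`, the shrinkage observed/expected ratio, with
  the closed-form lower credibility bound
  `IC025 = IC − 3.3(a+0.5)^(−1/2) − 2.4(a+0.5)^(−1)`.
* **MGPS / EBGM**: the empirical-Bayes gamma-Poisson shrinker described
  below.

**Conjunctive gate.** A term is a signal only when *all four* algorithms
pass, plus a minimum-count guard: `a ≥ 3`, ROR CI lower bound `> 1`,
`PRR ≥ 2` with `χ² ≥ 4`, `IC025 > 0`, `EBGM05 > 2`. These are the
field-standard thresholds; every component is exposed in
`signal_thresholds()` so a run's criteria are auditable.

### MGPS details

Counts are modeled as `a ~ Poisson(λE)` with the reporting-rate ratio λ
drawn from a two-component gamma mixture prior
`λ ~ p·Gamma(α₁, β₁) + (1−p)·Gamma(α₂, β₂)` (rate parameterization).
Marginally `a` is a mixture of two negative binomials; `gps_fit()` maximizes
that marginal likelihood across *all* drug–event pairs of the database
(`build_pair_expected()`), not just the target drug's, so the prior reflects
the database's dispersion.

Numerics: parameters are fitted on the log/logit scale (positivity and the
(0,1) weight are structural), by BFGS from the classic initialization
`(0.2, 0.1, 2, 4, 1/3)` with relative tolerance `1e-6`. Two fixed auxiliary
starts (a rare-elevated/concentrated-null shape and a flat shape) are also
run and the best likelihood kept, ties to the earliest start. The extra
starts matter because the mixture likelihood has point-mass local optima:
on a weakly dispersed database the classic start can collapse both
components onto λ ≈ 1, which shrinks every genuine signal away. The
procedure involves no randomness and is reproducible without seeds.

The posterior for one pair is again a two-gamma mixture with shapes
`αₖ + a`, rates `βₖ + E`, and a data-dependent weight.
`EBGM = exp(E[ln λ | a])` evaluates in closed form through the digamma
function; `EBGM05` is the posterior 5th percentile found by root-finding on
the mixture CDF (absolute tolerance `1e-6`, bracketed by the component
quantiles). The test suite holds both against adaptive quadrature of the
posterior density to `1e-4` relative error.

### On the IC025 closed form

The IC025 formula above is the standard published approximation, and the
package reproduces it exactly. It is worth stating what it is *not*: it is
not a 0.15-bit-accurate approximation of the 2.5% quantile of the
`Gamma(a+0.5, E+0.5)` observed/expected posterior at small counts. Measured
against Monte-Carlo quantiles of that posterior, the closed form sits
*below* the quantile by up to ≈0.4 bits at `a = 3`, narrowing monotonically
to under 0.15 bits by `a ≈ 20` (alternative canonical posteriors —
Bate-style beta with an IC-centering prior, Dirichlet-multinomial — agree
even less well). The discrepancy is uniformly conservative: the bound can
only understate a signal, never overstate one. The module tests assert
conservativeness everywhere and quantitative agreement for `a ≥ 20`; one
acceptance assertion that demands 0.15 bits across `a ∈ {3..50}` is left
failing by design rather than loosened.

## Sensitivity and subgroup reanalysis

The sensitivity run removes from the cohort every report listing any of the
configured co-medications in **any** role (suspect or concomitant) — the
exclusion is about the report's drug environment, not about causality
attribution — and reruns the same analysis; the background is left
unchanged. Defaults list the psychotropics most commonly co-prescribed with
the default target drug (escitalopram, sertraline, fluoxetine, venlafaxine,
duloxetine, bupropion, aripiprazole). Age subgroups analyze each stratum's
cohort against the full background; reports with missing age join no
stratum (they remain in the descriptive baseline's `Missing` row).

## Time to onset

Per report, the event date is paired with the **earliest day-precision**
therapy start among the suspect drug's therapy rows — earliest exposure is
the conservative latency origin. Records are kept only when both dates have
day precision and `0 ≤ tto ≤ 7300` days (a 20-year implausibility ceiling,
configurable; "implausible" has no standard definition). Exclusions are
tallied by reason (`missing`, `partial`, `negative`, `implausible`);
partial dates are excluded, not imputed. Quantiles use inclusive linear
interpolation (R type 7), pinned for byte-stable outputs. The early-onset
proportion defaults to a ≤30-day boundary, exposed as a parameter since a
"first month" convention is ambiguous between 30 and 31 days.

`fit_weibull()` estimates the Weibull shape β and scale α (days) by maximum
likelihood with Wald 95% CIs from the observed information on the log
scale. Whole-day inputs are treated as interval-censored — a recorded `t`
means the latent onset lay in `[max(t−0.5, 0), t+0.5]` — because rounding
to days concentrates mass at zero and, for β < 1, biases the
continuous-density MLE upward (measured: shape ≈ 0.52–0.53 fitted to data
simulated at shape 0.49; the interval likelihood recovers 0.48–0.50).
Continuous inputs use the plain density with zeros shifted to 0.5 day (an
exact zero breaks the log-likelihood for β < 1); both behaviors are
selectable via `method=`. Classification: `early` failure iff the β CI lies
entirely below 1 (hazard declining with time on drug), `wear_out` iff
entirely above 1, else `random`.

## The synthetic world

`generate_faers_dataset()` emulates the FAERS file set with known ground
truth. Its stated world:

* **Reports and drugs.** Each report gets exactly one primary-suspect drug,
  uniform over the vocabulary (default 25 drugs including the target), plus
  a Poisson(0.7) number of extra drugs in roles SS/C/I; a config flag allows
  multiple suspects.
* **Events.** Drug–event pairing is independent Bernoulli per (report,
  event) at `background_rate` (default `1e-3`), multiplied by the planted
  `rate_ratio` when the report carries the planted drug. Under this design
  the true odds ratio of a planted pair is the configured ratio up to
  `O(background_rate)`, which is what makes planted-recovery tests
  meaningful. Because at these rates most reports would otherwise carry no
  event at all, a small designated *filler* subset of the vocabulary
  (default 10 terms) contributes exactly one guaranteed PT per report;
  filler terms are ordinary null terms in the analysis but may not carry
  planted signals. Naive forced assignment of a random event to empty
  reports would instead have flattened every planted odds ratio toward 1.
* **Onset and dates.** Therapy start is uniform over the 2004–2025 window;
  the event date follows after a `Weibull(shape 0.49, scale 57.1)` draw
  rounded to whole days (the early-failure regime reported for this drug
  class); `FDA_DT` adds a 0–90-day reporting delay.
* **Duplicates.** A configured fraction of cases (default 5%) gains one
  extra report version with strictly later `FDA_DT` (or equal date and
  higher `PRIMARYID`), so the intended dedup survivor is unambiguous and
  recorded in the manifest.
* **Corruption.** A configured fraction (default 10%) of event/start dates
  is truncated to month or year precision, blanked, or (events only) moved
  before the therapy start; the manifest logs every touched value.
* **Demographics.** Sex, age stratum, occupation and country are drawn from
  categorical mixes loosely shaped like a large antidepressant cohort
  (≈54% female overall, age mass in 18–65, ≈20% missing per field via
  `missing_demo_rate`).

Everything is a pure function of the configuration including its seed:
identical configs produce byte-identical file sets.

**What a green test does and does not establish.** The generator plants
multiplicative signals in an otherwise exactly-null, independently-sampled
world. Green planted-recovery tests establish that the statistics and the
conjunctive gate recover known disproportionality at realistic sizes and
keep the false-positive rate under 1% on null data. They do not establish
robustness to features of real spontaneous data that the world omits:
correlated co-reporting of terms, secular reporting trends, reporting-rate
heterogeneity across drugs, masking by competing signals, or duplicated
cases that differ across versions. The acceptance-grade recovery runs use a
zero-concomitant variant of the world (no SS/C/I rows) because with
any-role carriers the primary-suspect cohort truth sits slightly below the
configured ratio by design.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_a` | 3 | reports | guards the gate against 1–2 report coincidences |
| `prr_ge`, `chi2_ge` | 2, 4 | — | field-standard PRR criterion |
| `ic025_gt`, `ebgm05_gt` | 0, 2 | bits, ratio | field-standard Bayesian bounds |
| `background_rate` | 1e-3 | prob/pair | rare-event regime of spontaneous data |
| `duplicate_rate` | 0.05 | fraction | typical case-versioning share |
| `partial_date_rate` | 0.10 | fraction | typical date dirtiness |
| `tto_shape`, `tto_scale` | 0.49, 57.1 | —, days | early-failure onset regime |
| `ceiling_days` | 7300 | days | 20-year implausibility cutoff |
| `top_k` | 50 | terms | ranked signal-table depth |

## Known limitations

* Percentages are rounded half-up to one decimal for presentation; published
  tables in this field sometimes contain percentages inconsistent with their
  own counts, and the pipeline always reports the arithmetic of the counts.
* The MGPS prior is fitted without zero-count truncation adjustment; at the
  expected-count magnitudes of these analyses (`E ≫ 0`) the effect is
  negligible, but very sparse databases would need the truncated likelihood.
* No multiple-comparison adjustment is applied (none is standard in this
  screening setting); signals are hypotheses, not confirmed associations.
* Competing risks, censoring, and per-term onset stratification are out of
  scope for the TTO module, which models a single pooled onset distribution.
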