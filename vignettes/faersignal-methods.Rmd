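---
title: "Methods: disproportionality screening of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The analysis model

Spontaneous-report databases such as FAERS have no denominator: we observe
only reports, not exposed patients. Disproportionality analysis therefore
asks whether a drug–event pair is reported *more often than expected given
the rest of the database*. The counting unit throughout this package is the
deduplicated report, contributing at most once per preferred term (PT) and
once per system organ class (SOC). For a target drug and a term, the 2×2
table (a, b, c, d) splits reports by target-drug suspect status and by
presence of the term; `a + b + c + d = N`, the total report count, held
fixed across PT and SOC levels.

### Deduplication

A case (CASEID) accumulates versions as follow-up information arrives. We
keep the version with the largest FDA receipt date (FDA_DT) and break exact
ties by the largest PRIMARYID — the FDA-recommended rule. The operation is
a pure function of the version set: idempotent and invariant to input
order, which the test suite checks by shuffling.

### Target-drug selection

Reports are selected when a drug mention matches the target name list
(default `AVACOPAN`, `TAVNEOS`; case-insensitive substring over the drug
name and active-ingredient fields) with role code PS (primary suspect).
"Related exclusively to the drug" admits a stricter reading, so
`sole_suspect` mode additionally excludes reports with any other PS/SS
drug; `primary_suspect` is the default because the selection is defined by
the primary-suspect role. Non-PS mentions of the target drug are left in
the comparator arm: they are a negligible share of comparator reports and
removing them would silently change N.

### Reporting odds ratio

ROR = (a·d)/(b·c) with the Woolf log-normal interval,
`exp(ln ROR ± z₀.₉₇₅ √(1/a + 1/b + 1/c + 1/d))`. When any cell is zero the
Haldane–Anscombe correction adds 0.5 to **all four** cells for both the
point estimate and the interval; non-degenerate tables are never
corrected, preserving the reciprocity property
ROR(a,b,c,d) · ROR(b,a,d,c) = 1 that the tests assert.

### BCPNN information component

The information component is IC = log₂ p(drug, event) / (p(drug) p(event)).
We evaluate the closed-form posterior expectation and variance under the
original BCPNN priors — Beta(1, 1) margins against Beta(α=2, β=2) style
totals, joint prior γ tuned so that E(IC) = 0 under independence — and
report IC025 = E(IC) − 2√V(IC). This closed form is finite for every cell
configuration including a = 0, needs no zero-cell correction, and is the
standard published definition of the method; the unit tests check it
against an independent transcription of the expectation and variance
formulas. A simplified shrinkage variant,
IC = log₂((a + 0.5)/(E[a] + 0.5)) with the usual credibility
approximation, is available via `bcpnn_ic(..., method = "shrinkage")` for
users who want the later-generation estimator; it is not used by the
default screen.

### Joint positivity rule

`signal_criteria()` defaults to a ≥ 3 cases, ROR 95% lower bound > 1, and
IC025 > 0; a term is a signal only when the ROR and BCPNN criteria hold
simultaneously. These defaults are consistent with every flagged row of
the bundled reference screen tables (all 33 PT signals have a ≥ 3,
ci_low > 1, ic025 > 0, and the one near-miss SOC with ic025 = −0.01 is
correctly not flagged). No multiple-testing adjustment is applied — the
convention of this screening literature, where flagged terms are
hypotheses for review, not confirmed effects; the pipeline manifest
carries an explicit note.

## Clinical-priority rubric

Five features, each 0/1/2 points: case count (<10 / 10–49 / ≥50), ROR025
(<2 / 2–<5 / ≥5), death fraction among the term's cases (<0.2 / 0.2–<0.5 /
≥0.5), designation (none / IME / DME), evidence grade (− / + / ++). Totals
0–4, 5–7, 8–10 map to weak, moderate, strong. The numeric cut points for
case count and ROR025 were fixed by requiring exact consistency with all
33 rows of the bundled priority table, which they achieve; the death-
fraction cuts are *not* identifiable from that table (every tabulated term
scores 0 there, the largest observed fraction being 4/23), so they are
explicit, documented parameters of `priority_rubric()` rather than
constants. Designations and evidence grades are curated inputs: they
encode regulatory lists (EMA IME/DME) and literature judgment that no
computation should fabricate.

## Subgroups and time to onset

Subgroup comparisons are 2×2 proportions of target-drug reports carrying
any PT of a term set, compared between two values of a report field —
reporter country by default. The package never infers race or ethnicity;
country is what the reports record, and outputs are labelled accordingly.
The default statistic is the Pearson chi-square without continuity
correction (df = 1); Yates correction is a flag, and `method = "auto"`
switches to Fisher's exact test when any expected cell is below 5. A term
set that saturates both groups (or appears in neither) is reported as
chi2 = 0, p = 1 — identical proportions — while an empty *group* is an
error, since no comparison exists.

Time to onset is the day difference between a report's event date and the
earliest full-precision therapy start date of the target drug, one
observation per report. Partial dates (YYYYMM, YYYY) are excluded rather
than imputed to a day, and negative intervals are excluded as implausible;
exclusion reasons are tallied. Quantiles use linear interpolation
(`stats::quantile` type 7), the convention that produces quarter-day IQR
values on integer data. Default bins are half-open intervals [0, 30),
[30, 60), [60, 90), [90, 180), [180, 360), ≥360 days — monthly at first,
where spontaneous-report onsets concentrate, then coarser.

## The synthetic generator

`generate_corpus()` draws reports from a two-stage multinomial: each
report names a suspect drug (the target with probability
`target_drug_share`, default 0.02, else one of 25 background drugs), then
reports 1–3 PTs drawn with replacement from a Zipf(1)-weighted vocabulary
of 200 toy PTs (cycled over 12 toy SOCs) and collapsed to unique
(report, PT) pairs. For the target drug the PT weights are multiplied by
the configured true rate ratios and renormalized. This is the simplest
model in which the true reporting odds ratio of every PT is available in
closed form: `sim_ground_truth()` records expected cells and the exact
true ROR, which differs slightly from the configured rate ratio because
of the renormalization (a rate-ratio-5 PT of rank 28 has true ROR ≈ 5.04).

Demographics emulate a US-dominated reporting base (country weights 0.893
US / 0.051 JP / 0.027 CA, sex split 62/38 female before 24.6% missingness,
age mixture peaking at 45–65); onset is log-normal with median 87 days and
sdlog 1.6, chosen to match the scale and IQR spread reported for the
avacopan screen; therapy start dates are uniform over 2022–2024, and FDA
receipt dates add a 7–90-day reporting lag. `duplicate_fraction` injects
extra case versions with later FDA_DTs (and, for half of them, PRIMARYID
ties) whose content rows are copied verbatim, so deduplication recovers
the original corpus exactly. Missing and partial (YYYYMM) dates exercise
the exclusion paths.

What the generator does **not** emulate: drug co-prescription structure,
correlated PT co-reporting (syndromes), reporting waves and stimulated
reporting, country-specific term preferences, and name variants beyond a
fixed brand/generic pair. Tests passing on this generator therefore
validate the *statistical machinery* — counting, estimation, calibration,
power — not robustness to the messiness of real FAERS text fields.

## Numerical and testing choices

* Rounding for report output is half-away-from-zero (so 46.985% prints as
  47.0%), at one decimal for percentages and two for ROR/CI/IC; internal
  values keep full precision.
* Percentages are computed against total reports, including for outcome
  codes (a report can carry several outcomes), matching the arithmetic of
  published descriptive tables.
* Ages convert to years via DEC×10, MON÷12, WK and DY by calendar factors;
  converted ages outside [0, 130] become missing with a warning.
* Calibration tests run 500 null replicates of 10,000 reports (target
  share 0.05, balanced two-country weights so both subgroup cells are
  populated): the Woolf 95% CI must cover the true ROR of 1 for 93–97% of
  terms with expected a ≥ 20, and the Pearson subgroup test must reject at
  3–7%. Power tests run 100 replicates of 50,000 reports with one PT at
  rate ratio 5 (expected a ≈ 58): the PT must be flagged in ≥95 and its CI
  must cover the true ROR in ≥90. These problem sizes make the binomial
  noise of the check itself small relative to the asserted bands.
* Generator convergence is asserted on standardized deviations (|z| < 4.5
  over all 200 terms) plus a 5% relative-error band restricted to terms
  whose expected counts make 5% at least four binomial SDs — a raw
  relative-error bound at small expected counts would be dominated by
  sampling noise rather than implementation error.

## Limitations

Disproportionality quantifies reporting associations, not incidence or
causation; the package deliberately stops at signal detection and
prioritization. The dedup rule cannot merge true duplicates filed under
different CASEIDs (no record linkage). Substring drug-name matching does
not normalize misspellings or combination products. And the bundled
reference tables are a fixed published surface used for regression
testing — reanalysis of live FAERS quarters will differ as the database
accumulates.
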