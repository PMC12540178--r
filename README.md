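# faersignal

Disproportionality-based signal detection for spontaneous adverse-event
report databases, built around the avacopan (complement C5a-receptor
antagonist, approved 2021 for ANCA-associated vasculitis) safety screen of
the FDA Adverse Event Reporting System (FAERS). The package is aimed at
pharmacovigilance analysts and methods researchers who need the full chain —
quarterly-file ingestion, deduplication, 2×2 screening statistics, clinical
prioritization, subgroup and onset analysis — as composable, tested R
functions rather than spreadsheet steps.

## What it computes

Every statistic is driven by the per-term 2×2 table of deduplicated report
counts:

|                    | term reported | term not reported |
|--------------------|---------------|-------------------|
| target drug        | a             | b                 |
| all other drugs    | c             | d                 |

* **Reporting odds ratio.** ROR = (a·d)/(b·c), with the Woolf (log-normal)
  95% interval `exp(ln ROR ± 1.96 · sqrt(1/a + 1/b + 1/c + 1/d))`. A
  Haldane–Anscombe correction (+0.5 to all cells) is applied only when a
  cell is zero.
* **BCPNN information component.** IC = log₂ P(drug, event) / (P(drug) P(event)),
  reported as the closed-form posterior expectation under the original
  BCPNN priors, with IC025 = E(IC) − 2·√V(IC). A simplified
  observed/expected shrinkage IC is available behind a flag.
* **Joint positivity rule.** A term is a signal when a ≥ 3, the ROR 95%
  lower bound exceeds 1, *and* IC025 exceeds 0 (all configurable via
  `signal_criteria()`).
* **Clinical priority.** Five features — case count, ROR025, death
  proportion, IME/DME designation, evidence grade — each scored 0/1/2;
  totals 0–4 / 5–7 / 8–10 map to weak / moderate / strong priority.
* **Subgroups and onset.** Pearson chi-square (Fisher fallback below
  expected count 5) for between-group comparison of an event's reporting
  proportion, and median/IQR plus binned distributions of days from therapy
  start to event, computed from full-precision dates only.

Deduplication follows FDA guidance: one report per CASEID, keeping the
largest FDA_DT and breaking ties by the highest PRIMARYID.

A synthetic FAERS-dialect generator (`sim_config()`, `generate_corpus()`)
emits DEMO/DRUG/REAC/THER/OUTC tables with configurable true
reporting-rate ratios, duplicate versions, missingness and onset
distribution, together with closed-form expected cells and true RORs —
so the whole pipeline is testable without downloading FAERS quarters.

## Worked example

```r
library(faersignal)

cfg <- sim_config(n_reports = 20000,
                  signal_spec = c(PT0028 = 5, PT0003 = 3), seed = 42)
corpus <- generate_corpus(cfg)
ds <- as_dataset(corpus)
ds
#> <faers_dataset> 20000 reports (410 target-drug), 38711 (report, PT) pairs, 37158 (report, SOC) pairs

screen <- run_screen(ds, "pt")
glance(screen)
#> # A tibble: 1 × 4
#>   level n_terms n_signals n_reports
#>   <chr>   <int>     <int>     <int>
#> 1 PT        154         3     20000

dplyr::filter(format_screen(screen), signal)
#> # A tibble: 3 × 14
#>   term   level     a     b     c     d   ror ci_low ci_high    ic ic025
#>   <chr>  <chr> <int> <int> <int> <int> <dbl>  <dbl>   <dbl> <dbl> <dbl>
#> 1 PT0003 PT      106   304  2121 17469  2.87   2.29    3.6   1.19  0.88
#> 2 PT0028 PT       22   388   208 19382  5.28   3.37    8.29  2     1.36
#> 3 PT0137 PT        5   405    52 19538  4.64   1.84   11.7   1.45  0.21
```

Both planted signals (true rate ratios 5 and 3) are recovered with point
estimates inside their intervals; `PT0137` is a false positive of the kind
an unadjusted screen produces — the screens deliberately apply no
multiple-testing correction, and the pipeline manifest notes this.

```r
obs <- onset_observations(ds)
glance(summarize_onset(obs$days))
#> # A tibble: 1 × 4
#>       n median    q1    q3
#>   <int>  <dbl> <dbl> <dbl>
#> 1    84   77.5  29.8  315.
```

The onset medians track the generator's log-normal model (median 87 days);
`autoplot()` on a screen gives a forest plot, and on an onset summary a
binned bar chart.

The bundled reference tables from the avacopan FAERS screen (2022 Q1 –
2024 Q4) — the 24-row SOC screen, the 33 PT-level signals, the priority
features, and the demographic breakdown of its 1,128 avacopan reports —
load via `reference_table()` and drive the regression tests:

```r
soc <- evaluate_signal(reference_table("soc_screen"))
sum(soc$signal)
#> [1] 6
```

## Scope notes

* PT→SOC mapping is a user-supplied two-column CSV (MedDRA is licensed);
  the generator emits a toy mapping.
* IME/DME designations and evidence grades are curated annotation inputs,
  not computed.
* PRR, EBGM/MGPS and regression-adjusted disproportionality are out of
  scope, as is record-linkage deduplication beyond the CASEID rule.
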