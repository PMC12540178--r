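Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous-report data: parsing of "$"-delimited quarterly
    tables, case-level deduplication, target-drug selection by role code,
    reporting odds ratio (ROR) with Woolf confidence intervals, the BCPNN
    information component with its lower credibility bound, a joint
    positivity rule, semi-quantitative clinical-priority scoring of
    detected signals, chi-square subgroup comparisons, and time-to-onset
    summaries. Includes a synthetic report generator with known ground
    truth for validating every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
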