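# Bundled reference tables from the avacopan FAERS screen (2022 Q1 -
# 2024 Q4): the SOC- and PT-level disproportionality tables, the
# clinical-priority feature table, and the demographic breakdown of the
# 1,128 avacopan reports. Used for regression tests of the positivity rule,
# the priority rubric, and the report formatters.

#' Load a bundled avacopan reference table
#'
#' @param name one of `"soc_screen"` (24 SOC rows: n, ROR with 95\% CI, IC
#'   with IC025), `"pt_screen"` (the 33 PT-level signal rows),
#'   `"priority_features"` (per-signal case counts, ROR025, deaths, IME/DME
#'   designation, evidence grade, and the reference priority score and
#'   category), `"demographics"` (reference case counts by sex, age group,
#'   outcome and country).
#' @return a tibble. Screen tables gain an `a = n` alias column so they
#'   feed [evaluate_signal()] directly.
#' @export
#' @examples
#' ref <- reference_table("pt_screen")
#' head(ref)
reference_table <- function(name = c("soc_screen", "pt_screen",
                                     "priority_features", "demographics")) {
  name <- match.arg(name)
  file <- c(soc_screen = "avacopan_soc_screen.csv",
            pt_screen = "avacopan_pt_screen.csv",
            priority_features = "avacopan_priority_features.csv",
            demographics = "avacopan_demographics.csv")[[name]]
  path <- system.file("extdata", file, package = "faersignal",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (name %in% c("soc_screen", "pt_screen")) {
    tab$a <- tab$n
  }
  tab
}
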