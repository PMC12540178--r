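# Descriptive summaries of the target-drug report population.

#' Summarize demographics of a report set
#'
#' Counts and percentages (of total reports, one decimal, half away from
#' zero) for sex, age group, serious outcomes, and the top reporter
#' countries. Age bins are half-open -- <18, \[18, 45), \[45, 65), >= 65,
#' unknown -- so boundary ages fall in the upper bin. Outcome percentages
#' are computed against total reports, not against the outcome rows, since
#' a report can carry several outcome codes.
#'
#' @param x a `faers_dataset` (target reports are summarized) or a case
#'   tibble with columns `sex`, `age_years`, `country`.
#' @param outcomes optional tibble (`primaryid`, `outcome`) when `x` is a
#'   case tibble.
#' @param top_countries how many countries to list (default 3).
#' @return tibble with columns `section`, `category`, `n`, `pct`.
#' @export
summarize_demographics <- function(x, outcomes = NULL, top_countries = 3) {
  if (inherits(x, "faers_dataset")) {
    cases <- filter(x$cases, .data$is_target)
    outcomes <- semi_join(x$outcomes, cases, by = "primaryid")
  } else {
    cases <- x
  }
  n_total <- nrow(cases)
  if (n_total == 0) {
    abort("Empty report set.", class = "faersignal_data_error")
  }
  pct <- function(n) round_half_up(100 * n / n_total, 1)
  row_of <- function(section, category, n) {
    tibble(section = section, category = category, n = n, pct = pct(n))
  }

  sex_lv <- c("female", "male", "missing")
  sex <- factor(ifelse(is.na(cases$sex), "missing", cases$sex),
                levels = sex_lv)
  sex_tab <- row_of("sex", sex_lv, as.integer(table(sex)))

  age_lv <- c("<18", "18-45", "45-65", ">=65", "unknown")
  age_grp <- dplyr::case_when(
    is.na(cases$age_years) ~ "unknown",
    cases$age_years < 18 ~ "<18",
    cases$age_years < 45 ~ "18-45",
    cases$age_years < 65 ~ "45-65",
    TRUE ~ ">=65")
  age_tab <- row_of("age", age_lv,
                    as.integer(table(factor(age_grp, levels = age_lv))))

  out_tab <- NULL
  if (!is.null(outcomes) && nrow(outcomes) > 0) {
    oc <- distinct(outcomes, .data$primaryid, .data$outcome) %>%
      count(.data$outcome, sort = TRUE)
    out_tab <- row_of("outcome", oc$outcome, oc$n)
  }

  ctry <- cases %>%
    filter(!is.na(.data$country)) %>%
    count(.data$country, sort = TRUE) %>%
    head(top_countries)
  ctry_tab <- row_of("country", ctry$country, ctry$n)

  bind_rows(row_of("total", "reports", n_total),
            sex_tab, age_tab, out_tab, ctry_tab)
}
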