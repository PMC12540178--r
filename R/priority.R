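# Semi-quantitative clinical-priority scoring of detected signals.
# Five features, each scored 0/1/2; totals 0-4 weak, 5-7 moderate,
# 8-10 strong.

#' Scoring rubric for clinical priority
#'
#' Each of the five features contributes 0, 1 or 2 points:
#' \itemize{
#'   \item case count: below `case_breaks[1]` scores 0, from
#'     `case_breaks[1]` to below `case_breaks[2]` scores 1, at or above
#'     `case_breaks[2]` scores 2 (default breaks 10, 50);
#'   \item ROR025 (lower 95\% ROR bound): breaks 2 and 5;
#'   \item proportion of deaths among the term's cases: breaks 0.2 and 0.5.
#'     These two cut points are the one part of the rubric not pinned down
#'     by published score tables (all tabulated terms score 0 on deaths),
#'     so they are explicit parameters;
#'   \item designation: none 0, IME (EMA Important Medical Event) 1, DME
#'     (Designated Medical Event) 2;
#'   \item evidence grade: "-" (disproportionality only) 0, "+" (other
#'     clinical evidence) 1, "++" (label / RCT / systematic-review support)
#'     2.
#' }
#'
#' @param case_breaks,ror025_breaks,death_breaks increasing length-2
#'   numeric cut points (half-open: score 1 starts at the first break,
#'   score 2 at the second).
#' @return an object of class `priority_rubric`.
#' @export
priority_rubric <- function(case_breaks = c(10, 50),
                            ror025_breaks = c(2, 5),
                            death_breaks = c(0.2, 0.5)) {
  chk <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] >= x[2]) {
      abort(sprintf("`%s` must be two increasing numeric cut points.", name),
            class = "faersignal_config_error")
    }
  }
  chk(case_breaks, "case_breaks")
  chk(ror025_breaks, "ror025_breaks")
  chk(death_breaks, "death_breaks")
  structure(list(case_breaks = case_breaks, ror025_breaks = ror025_breaks,
                 death_breaks = death_breaks),
            class = "priority_rubric")
}

#' Score signals on the five-feature clinical-priority scale
#'
#' Vectorized over rows of `features`. Sub-scores follow the rubric; the
#' total (0--10) maps to a category: weak for totals 0--4, moderate for
#' 5--7, strong for 8--10.
#'
#' @param features tibble (or data frame) with columns `case_count`
#'   (integer >= 0), `ror025` (positive), `death_fraction` (in \[0,1\]),
#'   `designation` (`"none"`, `"IME"`, `"DME"`), `evidence` (`"-"`, `"+"`,
#'   `"++"`). Extra columns are carried through.
#' @param rubric a [priority_rubric()].
#' @return the input with sub-score columns (`score_cases`, `score_ror025`,
#'   `score_deaths`, `score_designation`, `score_evidence`), `total`, and
#'   `category` appended.
#' @export
#' @examples
#' score_signal(data.frame(case_count = 61, ror025 = 2.08,
#'                         death_fraction = 0, designation = "none",
#'                         evidence = "++"))
score_signal <- function(features, rubric = priority_rubric()) {
  needed <- c("case_count", "ror025", "death_fraction", "designation",
              "evidence")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf("`features` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "faersignal_schema_error")
  }
  bad_desig <- setdiff(unique(features$designation), c("none", "IME", "DME"))
  if (length(bad_desig) > 0) {
    abort(sprintf("Unknown designation value(s): %s",
                  paste(bad_desig, collapse = ", ")),
          class = "faersignal_data_error")
  }
  bad_ev <- setdiff(unique(features$evidence), c("-", "+", "++"))
  if (length(bad_ev) > 0) {
    abort(sprintf("Unknown evidence value(s): %s",
                  paste(bad_ev, collapse = ", ")),
          class = "faersignal_data_error")
  }
  out <- as_tibble(features) %>%
    mutate(
      score_cases = findInterval(.data$case_count, rubric$case_breaks),
      score_ror025 = findInterval(.data$ror025, rubric$ror025_breaks),
      score_deaths = findInterval(.data$death_fraction, rubric$death_breaks),
      score_designation = dplyr::case_match(.data$designation,
                                            "none" ~ 0L, "IME" ~ 1L,
                                            "DME" ~ 2L),
      score_evidence = dplyr::case_match(.data$evidence,
                                         "-" ~ 0L, "+" ~ 1L, "++" ~ 2L),
      total = .data$score_cases + .data$score_ror025 + .data$score_deaths +
        .data$score_designation + .data$score_evidence,
      category = priority_category(.data$total))
  out
}

#' Map priority totals to categories
#'
#' @param total integer vector of totals in 0--10.
#' @return character vector: `"weak"` (<= 4), `"moderate"` (5--7),
#'   `"strong"` (>= 8).
#' @export
priority_category <- function(total) {
  dplyr::case_when(total <= 4 ~ "weak",
                   total <= 7 ~ "moderate",
                   TRUE ~ "strong")
}

#' Score all signals of a screen against curated annotations
#'
#' Joins the flagged signals of a disproportionality screen to curated
#' per-term annotations (deaths among the term's cases, IME/DME
#' designation, evidence grade), computes the death fraction, and scores
#' each signal. Ordering follows the screen (case count descending, then
#' term).
#'
#' @param results a `faers_screen` (or tibble with `term`, `a`, `ci_low`,
#'   `signal`).
#' @param annotations tibble with columns `term`, `deaths` (count),
#'   `designation`, `evidence`; every signal term must be present.
#' @param rubric a [priority_rubric()].
#' @return a tibble of class `faers_priorities`: one row per signal with
#'   features, sub-scores, `total` and `category`.
#' @export
screen_priorities <- function(results, annotations,
                              rubric = priority_rubric()) {
  sig <- filter(tidy_if_screen(results), .data$signal)
  if (nrow(sig) == 0) {
    out <- tibble(term = character(), case_count = integer(),
                  ror025 = double(), death_fraction = double(),
                  designation = character(), evidence = character(),
                  total = integer(), category = character())
    class(out) <- c("faers_priorities", class(out))
    return(out)
  }
  missing_terms <- setdiff(sig$term, annotations$term)
  if (length(missing_terms) > 0) {
    abort(sprintf("Missing annotation(s) for term(s): %s",
                  paste(missing_terms, collapse = ", ")),
          class = "faersignal_data_error")
  }
  feats <- sig %>%
    select("term", case_count = "a", ror025 = "ci_low") %>%
    inner_join(select(annotations, "term", "deaths", "designation",
                      "evidence"),
               by = "term") %>%
    mutate(death_fraction = .data$deaths / .data$case_count)
  out <- score_signal(feats, rubric)
  class(out) <- c("faers_priorities", class(out))
  out
}

#' Tally priority categories
#'
#' @param assessments output of [screen_priorities()] or [score_signal()].
#' @return tibble with one row per category (weak, moderate, strong; zero
#'   counts included).
#' @export
priority_tally <- function(assessments) {
  lv <- c("weak", "moderate", "strong")
  counts <- table(factor(assessments$category, levels = lv))
  tibble(category = lv, n = as.integer(counts))
}
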