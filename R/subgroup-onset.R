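# Subgroup 2x2 comparisons (chi-square / Fisher) and time-to-onset
# computation and summarization.

#' Two-by-two comparison of event occurrence between groups
#'
#' Pearson chi-square (df = 1, no continuity correction) by default; Yates
#' correction or Fisher's exact test by request. Under `method = "auto"`
#' the Pearson test is used unless any expected cell count is below 5, in
#' which case Fisher's exact test is substituted and recorded in the
#' `method` column.
#'
#' @param counts 2x2 matrix (rows = groups, columns = with/without event)
#'   of non-negative counts; both row margins must be positive.
#' @param method `"auto"`, `"pearson"`, `"yates"` or `"fisher"`.
#' @return one-row tibble: `chi2` (NA for Fisher), `p`, `method`, and the
#'   four counts (`a1`, `b1`, `a2`, `b2` -- group 1 / 2 with / without).
#' @export
#' @examples
#' chi_square_2x2(matrix(c(10, 30, 90, 70), nrow = 2))
chi_square_2x2 <- function(counts,
                           method = c("auto", "pearson", "yates", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0) ||
      any(is.na(counts))) {
    abort("`counts` must be a 2x2 matrix of non-negative counts.",
          class = "faersignal_usage_error")
  }
  if (any(rowSums(counts) == 0)) {
    abort("Undefined comparison: a group margin of the 2x2 table is zero.",
          class = "faersignal_stat_error")
  }
  if (any(colSums(counts) == 0)) {
    # event in every report of both groups (or in none): proportions are
    # identical by construction
    return(tibble(chi2 = 0, p = 1,
                  method = if (method == "auto") "pearson" else method,
                  a1 = counts[1, 1], b1 = counts[1, 2],
                  a2 = counts[2, 1], b2 = counts[2, 2]))
  }
  if (method == "auto") {
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    method <- if (any(expected < 5)) "fisher" else "pearson"
  }
  res <- switch(method,
    pearson = {
      ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
      list(chi2 = unname(ht$statistic), p = ht$p.value)
    },
    yates = {
      ht <- suppressWarnings(chisq.test(counts, correct = TRUE))
      list(chi2 = unname(ht$statistic), p = ht$p.value)
    },
    fisher = {
      ht <- fisher.test(counts)
      list(chi2 = NA_real_, p = ht$p.value)
    })
  tibble(chi2 = res$chi2, p = res$p, method = method,
         a1 = counts[1, 1], b1 = counts[1, 2],
         a2 = counts[2, 1], b2 = counts[2, 2])
}

#' Compare the occurrence of a term set between two report subgroups
#'
#' Restricted to target-drug reports. For each group (a value of a grouping
#' field of the case table, by default reporter country), the numerator is
#' the number of reports carrying at least one PT of `term_set` and the
#' denominator all the group's target reports. Delegates to
#' [chi_square_2x2()].
#'
#' @param dataset a `faers_dataset`.
#' @param term_set character vector of PTs defining the event of interest.
#' @param group_field column of `dataset$cases` to group by (default
#'   `"country"`).
#' @param group_a,group_b the two group labels to compare.
#' @param method passed to [chi_square_2x2()].
#' @return one-row tibble with group labels, per-group event/total counts,
#'   `chi2`, `p`, `method`.
#' @export
compare_subgroups <- function(dataset, term_set, group_field = "country",
                              group_a, group_b, method = "auto") {
  cases <- filter(dataset$cases, .data$is_target)
  grp <- cases[[group_field]]
  in_a <- !is.na(grp) & grp == group_a
  in_b <- !is.na(grp) & grp == group_b
  if (sum(in_a) == 0 || sum(in_b) == 0) {
    abort(sprintf("Empty subgroup: '%s' has %d and '%s' has %d target reports.",
                  group_a, sum(in_a), group_b, sum(in_b)),
          class = "faersignal_stat_error")
  }
  with_event <- unique(
    dataset$report_pt$primaryid[dataset$report_pt$pt %in% term_set])
  n_a <- sum(in_a); n_b <- sum(in_b)
  e_a <- sum(cases$primaryid[in_a] %in% with_event)
  e_b <- sum(cases$primaryid[in_b] %in% with_event)
  counts <- matrix(c(e_a, e_b, n_a - e_a, n_b - e_b), nrow = 2)
  test <- chi_square_2x2(counts, method = method)
  tibble(group_a = group_a, group_b = group_b,
         events_a = e_a, total_a = n_a, events_b = e_b, total_b = n_b,
         chi2 = test$chi2, p = test$p, method = test$method)
}

#' Days from therapy start to event
#'
#' Interval arithmetic is only performed on full-precision (YYYYMMDD)
#' dates; partial dates (YYYYMM, YYYY) and missing values are excluded
#' rather than given a fabricated day, and negative intervals (event before
#' start) are excluded as implausible. Vectorized.
#'
#' @param event_dt,start_dt character vectors of raw date strings.
#' @return tibble with `days` (integer, NA when excluded) and `reason`
#'   (`NA` when included, else `"missing"`, `"partial_date"`,
#'   `"negative"`).
#' @export
#' @examples
#' onset_days(c("20230131", "202301"), c("20230101", "20230101"))
onset_days <- function(event_dt, start_dt) {
  prec_e <- date_precision(event_dt)
  prec_s <- date_precision(start_dt)
  reason <- dplyr::case_when(
    prec_e == "missing" | prec_s == "missing" ~ "missing",
    prec_e == "partial" | prec_s == "partial" ~ "partial_date",
    TRUE ~ NA_character_)
  days <- rep(NA_integer_, length(reason))
  ok <- which(is.na(reason))
  if (length(ok) > 0) {
    d <- as.integer(parse_full_date(event_dt[ok]) -
                      parse_full_date(start_dt[ok]))
    neg <- d < 0
    days[ok[!neg]] <- d[!neg]
    reason[ok[neg]] <- "negative"
  }
  tibble(days = days, reason = reason)
}

#' Extract time-to-onset observations from a dataset
#'
#' One observation per target-drug report: days from the earliest
#' full-precision start date of the target drug to the report's event
#' date. Reports with missing, partial or negative intervals are excluded
#' with their reason tallied.
#'
#' @param dataset a `faers_dataset`.
#' @return tibble with `primaryid`, `days` for included reports; excluded
#'   counts are attached as attribute `"excluded"`.
#' @export
onset_observations <- function(dataset) {
  od <- onset_days(dataset$onset$event_dt, dataset$onset$start_dt)
  out <- tibble(primaryid = dataset$onset$primaryid, days = od$days) %>%
    filter(!is.na(.data$days))
  attr(out, "excluded") <- table(od$reason)
  out
}

#' Summarize a time-to-onset distribution
#'
#' Median and quartiles use linear-interpolation quantiles (type 7); the
#' binned distribution uses half-open day intervals \[e1, e2), ...,
#' \[ek, Inf) over the supplied edges.
#'
#' @param days integer vector of onset days (>= 0).
#' @param bin_edges increasing non-negative edges; the last bin is open.
#' @return an object of class `faers_onset_summary`: list with `n`,
#'   `median`, `q1`, `q3`, and `bins` (tibble: `bin`, `lower`, `upper`,
#'   `n`, `proportion`).
#' @export
#' @examples
#' summarize_onset(c(5, 40, 400))
summarize_onset <- function(days, bin_edges = c(0, 30, 60, 90, 180, 360)) {
  days <- days[!is.na(days)]
  if (length(days) == 0) {
    abort("No onset observations to summarize.",
          class = "faersignal_data_error")
  }
  if (is.unsorted(bin_edges, strictly = TRUE) || any(bin_edges < 0)) {
    abort("`bin_edges` must be strictly increasing and non-negative.",
          class = "faersignal_usage_error")
  }
  q <- unname(quantile(days, c(0.25, 0.5, 0.75), type = 7))
  lower <- bin_edges
  upper <- c(bin_edges[-1], Inf)
  counts <- vapply(seq_along(lower), function(i) {
    sum(days >= lower[i] & days < upper[i])
  }, integer(1))
  bins <- tibble(
    bin = ifelse(is.finite(upper),
                 sprintf("[%g, %g)", lower, upper),
                 sprintf(">= %g", lower)),
    lower = lower, upper = upper, n = counts,
    proportion = counts / length(days))
  structure(list(n = length(days), median = q[2], q1 = q[1], q3 = q[3],
                 bins = bins),
            class = "faers_onset_summary")
}

#' @export
print.faers_onset_summary <- function(x, ...) {
  cat(sprintf("<onset summary> n = %d, median %.1f days (IQR %.2f - %.2f)\n",
              x$n, x$median, x$q1, x$q3))
  print(x$bins)
  invisible(x)
}

#' Tidy methods for onset summaries
#'
#' `tidy()` returns the binned distribution, `glance()` the n/median/IQR
#' row.
#'
#' @param x a `faers_onset_summary`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.faers_onset_summary <- function(x, ...) x$bins

#' @rdname tidy.faers_onset_summary
#' @export
glance.faers_onset_summary <- function(x, ...) {
  tibble(n = x$n, median = x$median, q1 = x$q1, q3 = x$q3)
}
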