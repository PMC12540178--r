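# Disproportionality statistics: 2x2 contingency tables, ROR with Woolf
# confidence intervals, the BCPNN information component, and the joint
# positivity rule.

#' Positivity criteria for the joint signal rule
#'
#' A term is ROR-positive when its case count reaches `min_cases` and the
#' lower 95\% ROR bound exceeds `ror_lower_gt`; BCPNN-positive when IC025
#' exceeds `ic025_gt`. A signal requires both.
#'
#' @param min_cases minimum case count (default 3).
#' @param ror_lower_gt threshold the ROR 95\% lower bound must exceed
#'   (default 1).
#' @param ic025_gt threshold IC025 must exceed (default 0).
#' @return an object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_cases = 3L, ror_lower_gt = 1, ic025_gt = 0) {
  min_cases <- check_count(min_cases, "min_cases")
  structure(list(min_cases = min_cases, ror_lower_gt = ror_lower_gt,
                 ic025_gt = ic025_gt), class = "signal_criteria")
}

#' Build the 2x2 contingency table for one term
#'
#' Counts unique (report, term) incidence: `a` target-drug reports with the
#' term, `b` target reports without it, `c` comparator reports with it, `d`
#' comparator reports without it. Cells always sum to the dataset's total
#' report count.
#'
#' @param dataset a `faers_dataset`.
#' @param term a PT (or SOC for `level = "soc"`) present in the dataset.
#' @param level `"pt"` or `"soc"`.
#' @return one-row tibble with columns `term`, `level`, `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(dataset, term, level = c("pt", "soc")) {
  level <- tolower(match.arg(tolower(level), c("pt", "soc")))
  pairs <- if (level == "pt") dataset$report_pt else
    rename(dataset$report_soc, pt = "soc")
  if (!term %in% pairs$pt) {
    abort(sprintf("Term '%s' does not occur at the %s level.", term,
                  toupper(level)),
          class = "faersignal_lookup_error")
  }
  with_term <- pairs$primaryid[pairs$pt == term]
  target_ids <- dataset$cases$primaryid[dataset$cases$is_target]
  a <- sum(with_term %in% target_ids)
  c_ <- length(with_term) - a
  tibble(term = term, level = toupper(level),
         a = a, b = dataset$n_target - a,
         c = c_, d = dataset$n_total - dataset$n_target - c_)
}

#' Reporting odds ratio with Woolf 95\% confidence interval
#'
#' ROR = (a d) / (b c); the log-scale standard error is
#' sqrt(1/a + 1/b + 1/c + 1/d). When any cell is zero, the
#' Haldane--Anscombe correction (+0.5 to all four cells) is applied to both
#' the point estimate and the interval; tables with no zero cell are left
#' untouched. Vectorized over cells.
#'
#' @param a,b,c,d contingency cells (target-with, target-without,
#'   comparator-with, comparator-without).
#' @param z normal quantile for the interval (default the two-sided 95\%
#'   value 1.959964).
#' @return tibble with columns `ror`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' ror_ci(20, 80, 100, 900)
ror_ci <- function(a, b, c, d, z = qnorm(0.975)) {
  if (any(a + b == 0) || any(c + d == 0)) {
    abort("Undefined margin: a+b and c+d must both be positive.",
          class = "faersignal_stat_error")
  }
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  k <- ifelse(zero, 0.5, 0)
  a <- a + k; b <- b + k; c <- c + k; d <- d + k
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(ror = ror,
         ci_low = exp(log(ror) - z * se),
         ci_high = exp(log(ror) + z * se))
}

#' BCPNN information component with lower credibility bound
#'
#' The default `method = "bate"` evaluates the closed-form posterior
#' expectation and variance of the information component
#' IC = log2 P(drug, event) / (P(drug) P(event)) under the original BCPNN
#' Beta/Dirichlet priors (alpha1 = beta1 = 1, alpha = beta = 2,
#' gamma11 = 1, with gamma tuned so the prior IC expectation is 0); IC025 =
#' E(IC) - 2 sqrt(V(IC)). Finite for all cells including a = 0.
#' `method = "shrinkage"` is the simplified observed-to-expected form
#' IC = log2((a + 0.5) / (E\[a\] + 0.5)) with the credibility-interval
#' approximation IC025 = IC - 3.3 (a + 0.5)^-1/2 - 2 (a + 0.5)^-3/2.
#'
#' @param a,b,c,d contingency cells; vectorized.
#' @param method `"bate"` (default) or `"shrinkage"`.
#' @return tibble with columns `ic`, `ic025`.
#' @export
#' @examples
#' bcpnn_ic(20, 80, 100, 900)
bcpnn_ic <- function(a, b, c, d, method = c("bate", "shrinkage")) {
  method <- match.arg(method)
  n <- a + b + c + d
  if (any(n <= 0)) {
    abort("N must be positive.", class = "faersignal_stat_error")
  }
  cx <- a + b   # drug margin
  cy <- a + c   # event margin
  if (method == "bate") {
    alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2; gamma11 <- 1
    gamma <- gamma11 * (n + alpha) * (n + beta) /
      ((cx + alpha1) * (cy + beta1))
    e_ic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
                   ((n + gamma) * (cx + alpha1) * (cy + beta1)))
    v_ic <- ((n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
               (n - cx + alpha - alpha1) / ((cx + alpha1) * (1 + n + alpha)) +
               (n - cy + beta - beta1) / ((cy + beta1) * (1 + n + beta))) /
      log(2)^2
    tibble(ic = e_ic, ic025 = e_ic - 2 * sqrt(v_ic))
  } else {
    expected <- cx * cy / n
    ic <- log2((a + 0.5) / (expected + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
    tibble(ic = ic, ic025 = ic025)
  }
}

#' Apply the joint positivity rule
#'
#' Adds `ror_positive`, `bcpnn_positive` and `signal` flags to a results
#' table. `ror_positive` requires `a >= min_cases` and the 95\% lower ROR
#' bound above the threshold; `bcpnn_positive` requires IC025 above its
#' threshold; `signal` is their conjunction. Works on any tibble carrying
#' columns `a`, `ci_low`, `ic025` -- including fixtures of published
#' screen tables.
#'
#' @param results tibble with columns `a`, `ci_low`, `ic025`.
#' @param criteria a [signal_criteria()].
#' @return `results` with the three logical flag columns appended.
#' @export
evaluate_signal <- function(results, criteria = signal_criteria()) {
  stopifnot(all(c("a", "ci_low", "ic025") %in% names(results)))
  mutate(results,
         ror_positive = .data$a >= criteria$min_cases &
           .data$ci_low > criteria$ror_lower_gt,
         bcpnn_positive = .data$ic025 > criteria$ic025_gt,
         signal = .data$ror_positive & .data$bcpnn_positive)
}

#' Screen every term of a dataset for disproportionality
#'
#' Computes the 2x2 cells, ROR with 95\% CI, IC with IC025, and the joint
#' positivity flags for every term with at least one target-drug case at
#' the requested level. Deterministic: rows sorted by case count
#' descending, then term.
#'
#' @param dataset a `faers_dataset`.
#' @param level `"pt"` or `"soc"`.
#' @param criteria a [signal_criteria()].
#' @param ic_method passed to [bcpnn_ic()].
#' @return a tibble of class `faers_screen` with columns `term`, `level`,
#'   `a`, `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`, `ic`, `ic025`,
#'   `ror_positive`, `bcpnn_positive`, `signal`.
#' @export
run_screen <- function(dataset, level = c("pt", "soc"),
                       criteria = signal_criteria(),
                       ic_method = "bate") {
  level <- tolower(match.arg(tolower(level), c("pt", "soc")))
  if (dataset$n_total == 0) {
    abort("Empty dataset.", class = "faersignal_data_error")
  }
  pairs <- if (level == "pt") dataset$report_pt else
    rename(dataset$report_soc, pt = "soc")
  target_ids <- dataset$cases$primaryid[dataset$cases$is_target]
  counts <- pairs %>%
    mutate(is_target = .data$primaryid %in% target_ids) %>%
    group_by(term = .data$pt) %>%
    summarise(a = sum(.data$is_target), with_term = n(), .groups = "drop") %>%
    mutate(b = dataset$n_target - .data$a,
           c = .data$with_term - .data$a,
           d = dataset$n_total - dataset$n_target - .data$c) %>%
    filter(.data$a >= 1) %>%
    select(-"with_term")
  res <- bind_cols(
    counts,
    ror_ci(counts$a, counts$b, counts$c, counts$d),
    bcpnn_ic(counts$a, counts$b, counts$c, counts$d, method = ic_method))
  res <- evaluate_signal(res, criteria)
  res <- res %>%
    mutate(level = toupper(level), .after = "term") %>%
    arrange(desc(.data$a), .data$term)
  class(res) <- c("faers_screen", class(res))
  attr(res, "criteria") <- criteria
  attr(res, "n_total") <- dataset$n_total
  res
}

#' Summaries of screens and datasets
#'
#' `glance()` returns a one-row overview of a screen (terms screened,
#' signals flagged) or of a dataset (report and term counts). `tidy()` on a
#' screen returns the plain results tibble.
#'
#' @param x a `faers_screen` or `faers_dataset`.
#' @param ... unused.
#' @return a tibble.
#' @export
glance.faers_screen <- function(x, ...) {
  tibble(level = x$level[1], n_terms = nrow(x), n_signals = sum(x$signal),
         n_reports = attr(x, "n_total") %||% NA_integer_)
}

#' @rdname glance.faers_screen
#' @export
tidy.faers_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "faers_screen")
  attr(out, "criteria") <- NULL
  attr(out, "n_total") <- NULL
  out
}

#' Format a screen for report output
#'
#' Rounds ROR and CI bounds and IC / IC025 to two decimals (half away from
#' zero), the convention of published disproportionality tables. Internal
#' values keep full precision; this is a presentation layer only.
#'
#' @param screen a `faers_screen` (or compatible tibble).
#' @return tibble with formatted columns.
#' @export
format_screen <- function(screen) {
  screen %>%
    tidy_if_screen() %>%
    mutate(dplyr::across(dplyr::any_of(c("ror", "ci_low", "ci_high",
                                         "ic", "ic025")),
                         ~ round_half_up(.x, 2)))
}

tidy_if_screen <- function(x) {
  if (inherits(x, "faers_screen")) tidy(x) else x
}
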