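# ggplot2 displays for screens and onset summaries.

#' Forest-style plot of a disproportionality screen
#'
#' ROR point estimates with 95\% confidence intervals on a log axis, terms
#' ordered by case count, colored by the joint signal flag.
#'
#' @param object a `faers_screen`.
#' @param max_terms show at most this many terms (by case count).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.faers_screen <- function(object, max_terms = 30, ...) {
  df <- head(tidy(object), max_terms)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$term,
                                   color = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#c0392b",
                                           `FALSE` = "grey40"),
                                name = "signal") +
    ggplot2::labs(x = "ROR (95% CI, log scale)", y = NULL,
                  title = sprintf("%s-level disproportionality screen",
                                  df$level[1]))
}

#' Bar chart of a time-to-onset distribution
#'
#' @param object a `faers_onset_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.faers_onset_summary <- function(object, ...) {
  bins <- object$bins
  bins$bin <- factor(bins$bin, levels = bins$bin)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$proportion)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      x = "days from therapy start", y = "proportion of reports",
      title = sprintf("Time to onset (n = %d, median %.1f days)",
                      object$n, object$median))
}

#' @rdname autoplot.faers_screen
#' @param screen a `faers_screen`.
#' @export
plot_signal_forest <- function(screen, max_terms = 30) {
  autoplot(screen, max_terms = max_terms)
}

#' @rdname autoplot.faers_onset_summary
#' @param summary a `faers_onset_summary`.
#' @export
plot_onset_distribution <- function(summary) autoplot(summary)
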