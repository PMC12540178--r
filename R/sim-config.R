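#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines the generative model behind [generate_corpus()]: a two-stage
#' multinomial in which each report first names a suspect drug (the target
#' drug with probability `target_drug_share`, otherwise one of
#' `n_background_drugs` background drugs) and then reports 1--3 preferred
#' terms (PTs) drawn from a Zipf-weighted background vocabulary. For the
#' target drug, the per-PT weights are multiplied by the configured true
#' reporting-rate ratios and renormalized, so the true reporting odds ratio
#' of each PT is known in closed form and recorded as ground truth.
#'
#' @param n_reports number of distinct cases to generate (before duplicate
#'   versions are injected).
#' @param n_background_drugs number of background (comparator) drugs.
#' @param n_terms size of the toy PT vocabulary (`PT0001`, `PT0002`, ...).
#' @param n_socs number of toy system organ classes the PTs cycle through.
#' @param target_drug_share probability in (0,1) that a report names the
#'   target drug as primary suspect.
#' @param signal_spec named numeric vector of true reporting-rate ratios,
#'   names being PTs of the toy vocabulary (e.g. `c(PT0028 = 5)`); ratios
#'   must be >= 0. PTs not named have ratio 1 (null).
#' @param duplicate_fraction fraction in \[0,1) of cases that receive extra
#'   report versions sharing the CASEID (see [inject_duplicates()]).
#' @param missing_sex_fraction,missing_age_fraction,missing_date_fraction
#'   fractions in \[0,1) of reports with the field blanked. Dates (event and
#'   therapy start) are blanked independently.
#' @param partial_date_fraction fraction in \[0,1) of non-missing dates
#'   truncated to YYYYMM precision, exercising partial-date handling.
#' @param ss_fraction fraction in \[0,1) of reports carrying an additional
#'   secondary-suspect (SS) background drug, exercising `sole_suspect`
#'   selection.
#' @param onset_model list with elements `family` (only `"lognormal"`) and
#'   `meanlog`, `sdlog` on the log-day scale. The default has median 87
#'   days and an IQR ratio matching spontaneous-report onset data.
#' @param country_weights named non-negative weights over reporter-country
#'   codes; defaults approximate a US-dominated reporting base.
#' @param seed integer seed; the same config (including seed) always yields
#'   byte-identical output files.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_corpus()]
#' @export
#' @examples
#' cfg <- sim_config(n_reports = 2000, seed = 7)
#' cfg$target_drug_share
sim_config <- function(n_reports = 50000L,
                       n_background_drugs = 25L,
                       n_terms = 200L,
                       n_socs = 12L,
                       target_drug_share = 0.02,
                       signal_spec = NULL,
                       duplicate_fraction = 0.05,
                       missing_sex_fraction = 0.246,
                       missing_age_fraction = 0.288,
                       missing_date_fraction = 0.5,
                       partial_date_fraction = 0.05,
                       ss_fraction = 0.05,
                       onset_model = list(family = "lognormal",
                                          meanlog = log(87), sdlog = 1.6),
                       country_weights = c(US = 0.893, JP = 0.051, CA = 0.027,
                                           GB = 0.015, FR = 0.014),
                       seed = 1L) {
  n_reports <- check_count(n_reports, "n_reports")
  n_background_drugs <- check_count(n_background_drugs, "n_background_drugs")
  n_terms <- check_count(n_terms, "n_terms")
  n_socs <- check_count(n_socs, "n_socs")
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.numeric(target_drug_share) || length(target_drug_share) != 1L ||
      is.na(target_drug_share) ||
      target_drug_share <= 0 || target_drug_share >= 1) {
    abort("`target_drug_share` must be a fraction in (0, 1).",
          class = "faersignal_config_error")
  }
  check_fraction(duplicate_fraction, "duplicate_fraction")
  check_fraction(missing_sex_fraction, "missing_sex_fraction")
  check_fraction(missing_age_fraction, "missing_age_fraction")
  check_fraction(missing_date_fraction, "missing_date_fraction")
  check_fraction(partial_date_fraction, "partial_date_fraction")
  check_fraction(ss_fraction, "ss_fraction")
  if (!is.numeric(country_weights) || is.null(names(country_weights)) ||
      any(country_weights < 0) || sum(country_weights) <= 0) {
    abort("`country_weights` must be named non-negative weights with sum > 0.",
          class = "faersignal_config_error")
  }
  if (!is.list(onset_model) ||
      !identical(onset_model$family, "lognormal") ||
      !is.numeric(onset_model$meanlog) || !is.numeric(onset_model$sdlog) ||
      onset_model$sdlog <= 0) {
    abort("`onset_model` must be list(family = \"lognormal\", meanlog, sdlog) with sdlog > 0.",
          class = "faersignal_config_error")
  }
  vocab <- sprintf("PT%04d", seq_len(n_terms))
  if (!is.null(signal_spec)) {
    if (!is.numeric(signal_spec) || is.null(names(signal_spec)) ||
        any(signal_spec < 0)) {
      abort("`signal_spec` must be a named numeric vector of rate ratios >= 0.",
            class = "faersignal_config_error")
    }
    unknown <- setdiff(names(signal_spec), vocab)
    if (length(unknown) > 0) {
      abort(sprintf("`signal_spec` names PTs outside the vocabulary: %s.",
                    paste(unknown, collapse = ", ")),
            class = "faersignal_config_error")
    }
  }
  structure(
    list(n_reports = n_reports, n_background_drugs = n_background_drugs,
         n_terms = n_terms, n_socs = n_socs,
         target_drug_share = target_drug_share,
         signal_spec = signal_spec,
         duplicate_fraction = duplicate_fraction,
         missing_sex_fraction = missing_sex_fraction,
         missing_age_fraction = missing_age_fraction,
         missing_date_fraction = missing_date_fraction,
         partial_date_fraction = partial_date_fraction,
         ss_fraction = ss_fraction,
         onset_model = onset_model,
         country_weights = country_weights,
         seed = seed),
    class = "sim_config")
}

# Toy vocabulary with Zipf(1) background weights; PT i belongs to SOC
# ((i - 1) mod n_socs) + 1.
sim_vocabulary <- function(config) {
  i <- seq_len(config$n_terms)
  w <- 1 / i
  tibble(
    pt = sprintf("PT%04d", i),
    soc = sprintf("SOC%02d", ((i - 1L) %% config$n_socs) + 1L),
    p_background = w / sum(w)
  )
}

# Rate-ratio vector aligned with the vocabulary.
sim_rate_ratios <- function(config, vocab = sim_vocabulary(config)) {
  rr <- rep(1, nrow(vocab))
  if (!is.null(config$signal_spec)) {
    rr[match(names(config$signal_spec), vocab$pt)] <- unname(config$signal_spec)
  }
  rr
}

# Probability that a PT with per-draw probability p appears at least once
# in a report, marginal over the uniform 1..3 draw count.
pt_incidence <- function(p) {
  (p + (1 - (1 - p)^2) + (1 - (1 - p)^3)) / 3
}

#' Expected contingency cells under a generator configuration
#'
#' Closed-form ground truth for the two-stage multinomial model: per-PT
#' expected 2x2 cells (target with / target without / comparator with /
#' comparator without the PT) and the exact true reporting odds ratio
#' implied by the renormalized target PT distribution.
#'
#' @param config a [sim_config()].
#' @return tibble with columns `pt`, `soc`, `rate_ratio`, `exp_a`, `exp_b`,
#'   `exp_c`, `exp_d`, `true_ror`.
#' @export
sim_ground_truth <- function(config) {
  vocab <- sim_vocabulary(config)
  rr <- sim_rate_ratios(config, vocab)
  p_bg <- vocab$p_background
  p_tg <- p_bg * rr / sum(p_bg * rr)
  q_tg <- pt_incidence(p_tg)
  q_bg <- pt_incidence(p_bg)
  n_t <- config$n_reports * config$target_drug_share
  n_c <- config$n_reports - n_t
  tibble(
    pt = vocab$pt, soc = vocab$soc, rate_ratio = rr,
    exp_a = n_t * q_tg, exp_b = n_t * (1 - q_tg),
    exp_c = n_c * q_bg, exp_d = n_c * (1 - q_bg),
    true_ror = (q_tg / (1 - q_tg)) / (q_bg / (1 - q_bg))
  )
}
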