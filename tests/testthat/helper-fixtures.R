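# Small in-code fixtures shared across test files.

make_cases <- function(primaryid, caseid = primaryid, fda_dt = 20230101L,
                       sex = NA_character_, age_years = NA_real_,
                       country = "US", event_dt = NA_character_) {
  tibble::tibble(primaryid = as.integer(primaryid),
                 caseid = as.integer(caseid),
                 fda_dt = as.integer(fda_dt),
                 sex = sex, age_years = age_years, country = country,
                 event_dt = event_dt)
}

make_drugs <- function(primaryid, name, role_code, drug_seq = NULL,
                       prod_ai = NA_character_) {
  n <- length(primaryid)
  tibble::tibble(primaryid = as.integer(primaryid),
                 drug_seq = as.integer(drug_seq %||% seq_len(n)),
                 role_code = role_code, name = name, prod_ai = prod_ai)
}

make_events <- function(primaryid, pt) {
  tibble::tibble(primaryid = as.integer(primaryid), pt = pt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny deterministic dataset: 10 reports, 4 target (ids 1-4).
tiny_dataset <- function() {
  demo <- make_cases(1:10)
  drugs <- make_drugs(
    primaryid = 1:10,
    name = c(rep("AVACOPAN", 4), rep("OTHER DRUG", 6)),
    role_code = "PS", drug_seq = 1L)
  # term X: 2 target + 3 comparator reports; term Y on one target report
  events <- make_events(c(1, 2, 5, 6, 7, 1), c(rep("X", 5), "Y"))
  term_map <- tibble::tibble(pt = c("X", "Y"), soc = c("S1", "S1"))
  build_dataset(demo, drugs, events, term_map)
}

# Independent transcription of the BCPNN closed-form posterior moments
# (priors alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1, gamma tuned to
# prior independence), used as the oracle for bcpnn_ic().
oracle_bate_ic <- function(a, b, c, d) {
  C <- a + b + c + d
  cx <- a + b
  cy <- a + c
  g <- 1 * (C + 2) * (C + 2) / ((cx + 1) * (cy + 1))
  eic <- log2((a + 1) * (C + 2) * (C + 2) / ((C + g) * (cx + 1) * (cy + 1)))
  vic <- ((C - a + g - 1) / ((a + 1) * (1 + C + g)) +
            (C - cx + 2 - 1) / ((cx + 1) * (1 + C + 2)) +
            (C - cy + 2 - 1) / ((cy + 1) * (1 + C + 2))) / log(2)^2
  list(ic = eic, ic025 = eic - 2 * sqrt(vic))
}

# Brute-force screen: per-term loop over build_contingency + statistics.
brute_force_screen <- function(dataset, level = "pt") {
  pairs <- if (level == "pt") dataset$report_pt else
    dplyr::rename(dataset$report_soc, pt = "soc")
  target_ids <- dataset$cases$primaryid[dataset$cases$is_target]
  terms <- sort(unique(pairs$pt))
  rows <- lapply(terms, function(tm) {
    ct <- build_contingency(dataset, tm, level)
    if (ct$a < 1) return(NULL)
    cbind(ct, ror_ci(ct$a, ct$b, ct$c, ct$d),
          bcpnn_ic(ct$a, ct$b, ct$c, ct$d))
  })
  out <- evaluate_signal(dplyr::bind_rows(rows), signal_criteria())
  out[order(-out$a, out$term), ]
}
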