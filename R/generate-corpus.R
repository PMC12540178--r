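# Synthetic spontaneous-report corpus generation in the FAERS dialect.

TARGET_GENERIC <- "AVACOPAN"
TARGET_BRAND <- "TAVNEOS"

#' Generate a synthetic spontaneous-report corpus with known ground truth
#'
#' Draws a corpus of adverse-event reports under the two-stage multinomial
#' model of [sim_config()]: each case names a primary-suspect drug, reports
#' one to three preferred terms, and carries demographics with configured
#' missingness, therapy start and event dates (log-normal onset), outcome
#' codes, and reporter country. If `config$duplicate_fraction > 0`,
#' additional report versions sharing CASEIDs are injected via
#' [inject_duplicates()], so deduplication is exercised downstream.
#'
#' @param config a [sim_config()].
#' @return an object of class `faers_corpus`: a list of typed tibbles
#'   `demo`, `drug`, `reac`, `ther`, `outc`, the `term_map` (pt, soc), the
#'   `ground_truth` from [sim_ground_truth()], and the `config`.
#' @seealso [write_corpus()], [build_dataset()]
#' @export
#' @examples
#' corpus <- generate_corpus(sim_config(n_reports = 500, seed = 3))
#' nrow(corpus$demo)
generate_corpus <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().",
          class = "faersignal_config_error")
  }
  vocab <- sim_vocabulary(config)
  rr <- sim_rate_ratios(config, vocab)
  p_bg <- vocab$p_background
  p_tg <- p_bg * rr / sum(p_bg * rr)

  corpus <- withr::with_seed(config$seed, {
    n <- config$n_reports
    caseid <- 10000000L + seq_len(n)
    primaryid <- caseid * 10L + 1L
    is_target <- runif(n) < config$target_drug_share

    # --- events: 1-3 PT draws per report, distribution by suspect drug ---
    m <- sample(1:3, n, replace = TRUE)
    rep_pid <- rep(primaryid, m)
    rep_tgt <- rep(is_target, m)
    draw <- integer(length(rep_pid))
    draw[rep_tgt] <- sample.int(config$n_terms, sum(rep_tgt),
                                replace = TRUE, prob = p_tg)
    draw[!rep_tgt] <- sample.int(config$n_terms, sum(!rep_tgt),
                                 replace = TRUE, prob = p_bg)
    reac <- distinct(tibble(primaryid = rep_pid, pt = vocab$pt[draw]))

    # --- drugs: primary suspect + optional SS + Poisson concomitants ---
    bg_names <- sprintf("BACKGROUND DRUG %03d", seq_len(config$n_background_drugs))
    bg_ai <- sprintf("INGREDIENT %03d", seq_len(config$n_background_drugs))
    bg_idx <- sample.int(config$n_background_drugs, n, replace = TRUE)
    use_brand <- runif(n) < 0.3
    ps_name <- ifelse(is_target,
                      ifelse(use_brand, TARGET_BRAND, TARGET_GENERIC),
                      bg_names[bg_idx])
    ps_ai <- ifelse(is_target, TARGET_GENERIC, bg_ai[bg_idx])
    drug <- tibble(primaryid = primaryid, drug_seq = 1L, role_code = "PS",
                   name = ps_name, prod_ai = ps_ai)
    has_ss <- runif(n) < config$ss_fraction
    if (any(has_ss)) {
      ss_idx <- sample.int(config$n_background_drugs, sum(has_ss), replace = TRUE)
      drug <- bind_rows(drug, tibble(
        primaryid = primaryid[has_ss], drug_seq = 2L, role_code = "SS",
        name = bg_names[ss_idx], prod_ai = bg_ai[ss_idx]))
    }
    n_con <- rpois(n, 0.7)
    if (sum(n_con) > 0) {
      con_pid <- rep(primaryid, n_con)
      con_seq <- unlist(lapply(n_con[n_con > 0], function(k) seq_len(k) + 2L),
                        use.names = FALSE)
      con_idx <- sample.int(config$n_background_drugs, sum(n_con), replace = TRUE)
      drug <- bind_rows(drug, tibble(
        primaryid = con_pid, drug_seq = con_seq, role_code = "C",
        name = bg_names[con_idx], prod_ai = bg_ai[con_idx]))
    }
    drug <- arrange(drug, .data$primaryid, .data$drug_seq)

    # --- demographics ---
    sex <- ifelse(runif(n) < 0.623, "female", "male")
    sex[runif(n) < config$missing_sex_fraction] <- NA_character_
    age_bin <- sample.int(4L, n, replace = TRUE,
                          prob = c(0.016, 0.188, 0.410, 0.386))
    lo <- c(0, 18, 45, 65)[age_bin]
    hi <- c(18, 45, 65, 90)[age_bin]
    age_years <- floor(lo + runif(n) * (hi - lo))
    # infants carry month-precision ages so unit conversion round-trips
    infant <- age_years < 2
    age_years[infant] <- floor(runif(sum(infant)) * 24) / 12
    age_years[runif(n) < config$missing_age_fraction] <- NA_real_
    country <- sample(names(config$country_weights), n, replace = TRUE,
                      prob = config$country_weights)

    # --- dates: therapy start, log-normal onset, reporting lag ---
    start_date <- as.Date("2022-01-01") + floor(runif(n) * 900)
    onset <- floor(rlnorm(n, config$onset_model$meanlog,
                          config$onset_model$sdlog))
    event_date <- start_date + onset
    fda_dt <- as.integer(format(event_date + sample(7:90, n, replace = TRUE),
                                "%Y%m%d"))
    event_dt <- obscure_dates(format(event_date, "%Y%m%d"),
                              config$missing_date_fraction,
                              config$partial_date_fraction)
    start_dt <- obscure_dates(format(start_date, "%Y%m%d"),
                              config$missing_date_fraction,
                              config$partial_date_fraction)

    demo <- tibble(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
                   sex = sex, age_years = age_years, country = country,
                   event_dt = event_dt)
    ther <- tibble(primaryid = primaryid, dsg_drug_seq = 1L,
                   start_dt = start_dt)

    # --- outcomes: independent per-code draws ---
    out_p <- c(death = 0.069, `life-threatening` = 0.004,
               hospitalization = 0.195, disability = 0.002, other = 0.73)
    outc <- purrr::map(names(out_p), function(o) {
      hit <- runif(n) < out_p[[o]]
      tibble(primaryid = primaryid[hit], outcome = o)
    })
    outc <- arrange(bind_rows(outc), .data$primaryid, .data$outcome)

    list(demo = demo, drug = drug, reac = arrange(reac, .data$primaryid, .data$pt),
         ther = ther, outc = outc)
  })

  corpus$term_map <- select(vocab, "pt", "soc")
  corpus$ground_truth <- sim_ground_truth(config)
  corpus$config <- config
  class(corpus) <- "faers_corpus"
  if (config$duplicate_fraction > 0) {
    corpus <- inject_duplicates(corpus, config$duplicate_fraction,
                                seed = config$seed + 1L)
  }
  corpus
}

# Blank a fraction of dates, truncate a further fraction to YYYYMM.
obscure_dates <- function(x, missing_fraction, partial_fraction) {
  n <- length(x)
  x[runif(n) < missing_fraction] <- NA_character_
  part <- !is.na(x) & runif(n) < partial_fraction
  x[part] <- substr(x[part], 1, 6)
  x
}

#' Inject duplicate report versions into a corpus
#'
#' For a sampled fraction of cases, adds report versions sharing the CASEID
#' with a strictly later FDA receipt date (FDA_DT); for half of those cases
#' a third version ties on both CASEID and FDA_DT but has a higher
#' PRIMARYID. Drug, reaction, therapy and outcome rows are copied verbatim
#' under the new PRIMARYIDs, so deduplication recovers the original report
#' content regardless of which version survives.
#'
#' @param corpus a `faers_corpus`.
#' @param fraction fraction in \[0,1) of cases to duplicate.
#' @param seed integer seed for the case sample.
#' @return the corpus with duplicate versions appended (rows ordered by
#'   primaryid for reproducibility).
#' @export
inject_duplicates <- function(corpus, fraction, seed = 1L) {
  check_fraction(fraction, "fraction")
  if (fraction == 0) return(corpus)
  withr::with_seed(seed, {
    n_dup <- floor(nrow(corpus$demo) * fraction)
    if (n_dup == 0) return(corpus)
    pick <- sort(sample.int(nrow(corpus$demo), n_dup))
    base <- corpus$demo[pick, ]
    v2 <- mutate(base,
                 primaryid = .data$caseid * 10L + 2L,
                 fda_dt = bump_yyyymmdd(.data$fda_dt,
                                        sample(30:200, n_dup, replace = TRUE)))
    tie <- head(seq_len(n_dup), ceiling(n_dup / 2))
    v3 <- mutate(v2[tie, ], primaryid = .data$caseid * 10L + 3L)
    new_versions <- bind_rows(v2, v3)
    pid_map <- tibble(
      primaryid = base$primaryid[match(new_versions$caseid, base$caseid)],
      new_pid = new_versions$primaryid)
    copy_rows <- function(tab) {
      extra <- inner_join(tab, pid_map, by = "primaryid",
                          relationship = "many-to-many")
      extra <- select(mutate(extra, primaryid = .data$new_pid), -"new_pid")
      arrange(bind_rows(tab, extra), .data$primaryid)
    }
    corpus$demo <- arrange(bind_rows(corpus$demo, new_versions),
                           .data$primaryid)
    for (t in c("drug", "reac", "ther", "outc")) {
      corpus[[t]] <- copy_rows(corpus[[t]])
    }
    corpus
  })
}

# Add day offsets to integer YYYYMMDD dates.
bump_yyyymmdd <- function(x, days) {
  d <- as.Date(sprintf("%08d", x), format = "%Y%m%d") + days
  as.integer(format(d, "%Y%m%d"))
}

#' Write a synthetic corpus in the FAERS quarterly ASCII dialect
#'
#' Serializes the corpus as "$"-delimited text tables (`DEMO.txt`,
#' `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt`) with FAERS column
#' headers, plus the toy PT-to-SOC map (`pt_soc_map.csv`) and the generator
#' ground truth (`ground_truth.json`). Output is byte-identical for a fixed
#' configuration.
#'
#' @param corpus a `faers_corpus`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  demo <- transmute_demo_raw(corpus$demo)
  drug <- with(corpus$drug, tibble(PRIMARYID = primaryid, DRUG_SEQ = drug_seq,
                                   ROLE_COD = role_code, DRUGNAME = name,
                                   PROD_AI = prod_ai))
  reac <- with(corpus$reac, tibble(PRIMARYID = primaryid, PT = pt))
  ther <- with(corpus$ther, tibble(PRIMARYID = primaryid,
                                   DSG_DRUG_SEQ = dsg_drug_seq,
                                   START_DT = start_dt))
  outc <- with(corpus$outc, tibble(PRIMARYID = primaryid,
                                   OUTC_COD = outcome_to_code(outcome)))
  wr <- function(x, name) {
    readr::write_delim(x, file.path(dir, name), delim = "$", na = "")
  }
  wr(demo, "DEMO.txt"); wr(drug, "DRUG.txt"); wr(reac, "REAC.txt")
  wr(ther, "THER.txt"); wr(outc, "OUTC.txt")
  readr::write_csv(corpus$term_map, file.path(dir, "pt_soc_map.csv"))
  jsonlite::write_json(
    list(ground_truth = corpus$ground_truth,
         config = config_as_list(corpus$config)),
    file.path(dir, "ground_truth.json"),
    digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

transmute_demo_raw <- function(demo) {
  age <- demo$age_years
  months <- !is.na(age) & age < 2
  tibble(
    PRIMARYID = demo$primaryid,
    CASEID = demo$caseid,
    FDA_DT = demo$fda_dt,
    SEX = dplyr::case_match(demo$sex, "female" ~ "F", "male" ~ "M",
                            .default = NA_character_),
    AGE = ifelse(months, round(age * 12), age),
    AGE_COD = ifelse(is.na(age), NA_character_, ifelse(months, "MON", "YR")),
    OCCR_COUNTRY = demo$country,
    EVENT_DT = demo$event_dt
  )
}

outcome_to_code <- function(x) {
  dplyr::case_match(x, "death" ~ "DE", "life-threatening" ~ "LT",
                    "hospitalization" ~ "HO", "disability" ~ "DS",
                    "other" ~ "OT")
}

code_to_outcome <- function(x) {
  dplyr::case_match(x, "DE" ~ "death", "LT" ~ "life-threatening",
                    "HO" ~ "hospitalization", "DS" ~ "disability",
                    .default = "other")
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$country_weights <- as.list(out$country_weights)
  out$signal_spec <- if (is.null(out$signal_spec)) NULL else
    as.list(out$signal_spec)
  out
}

#' @export
print.faers_corpus <- function(x, ...) {
  cat(sprintf(
    "<faers_corpus> %d report versions, %d cases, %d drugs, %d (report, PT) pairs\n",
    nrow(x$demo), length(unique(x$demo$caseid)),
    length(unique(x$drug$name)), nrow(x$reac)))
  invisible(x)
}
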