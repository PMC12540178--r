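# Parsing, deduplication and assembly of FAERS-dialect quarterly tables.

faers_schemas <- list(
  demo = list(required = c("PRIMARYID", "CASEID", "FDA_DT", "SEX", "AGE",
                           "AGE_COD", "OCCR_COUNTRY"),
              optional = "EVENT_DT"),
  drug = list(required = c("PRIMARYID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME"),
              optional = "PROD_AI"),
  reac = list(required = c("PRIMARYID", "PT"), optional = character()),
  ther = list(required = c("PRIMARYID", "DSG_DRUG_SEQ", "START_DT"),
              optional = character()),
  outc = list(required = c("PRIMARYID", "OUTC_COD"), optional = character())
)

#' Read one FAERS-dialect quarterly ASCII table
#'
#' Parses a "$"-delimited text table with a header row and returns typed
#' records. Demographic rows are converted to analysis units: `SEX` F/M to
#' `female`/`male`, `AGE` + `AGE_COD` to years (codes DEC, YR, MON, WK, DY,
#' HR), ages outside \[0, 130\] years dropped to missing with a warning.
#' Dates are kept as raw strings so partial (YYYYMM / YYYY) precision is
#' preserved; unparseable dates never fail the read. Outcome codes DE, LT,
#' HO, DS, OT map to death, life-threatening, hospitalization, disability,
#' other.
#'
#' @param path file path.
#' @param table_kind one of `"demo"`, `"drug"`, `"reac"`, `"ther"`,
#'   `"outc"` (case-insensitive).
#' @return a tibble of typed records; zero rows (with a warning) for an
#'   empty file.
#' @export
read_faers_table <- function(path, table_kind) {
  table_kind <- tolower(table_kind)
  if (!table_kind %in% names(faers_schemas)) {
    abort(sprintf("Unknown table_kind '%s'.", table_kind),
          class = "faersignal_usage_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "faersignal_io_error")
  }
  schema <- faers_schemas[[table_kind]]
  header_line <- readLines(path, n = 1L)
  if (length(header_line) == 0L) {
    warn(sprintf("Empty file: %s", path))
    return(empty_faers_records(table_kind))
  }
  header <- toupper(trimws(strsplit(header_line, "$", fixed = TRUE)[[1]]))
  missing_cols <- setdiff(schema$required, header)
  if (length(missing_cols) > 0) {
    abort(sprintf("Table '%s' is missing mandatory column(s): %s",
                  table_kind, paste(missing_cols, collapse = ", ")),
          class = "faersignal_schema_error")
  }
  raw <- readr::read_delim(
    path, delim = "$", na = c("", "NA"), trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE)
  names(raw) <- toupper(names(raw))
  if (nrow(raw) == 0L) {
    warn(sprintf("No data rows in %s", path))
    return(empty_faers_records(table_kind))
  }
  type_faers_records(raw, table_kind)
}

empty_faers_records <- function(table_kind) {
  proto <- switch(table_kind,
    demo = tibble(primaryid = integer(), caseid = integer(),
                  fda_dt = integer(), sex = character(),
                  age_years = double(), country = character(),
                  event_dt = character()),
    drug = tibble(primaryid = integer(), drug_seq = integer(),
                  role_code = character(), name = character(),
                  prod_ai = character()),
    reac = tibble(primaryid = integer(), pt = character()),
    ther = tibble(primaryid = integer(), dsg_drug_seq = integer(),
                  start_dt = character()),
    outc = tibble(primaryid = integer(), outcome = character()))
  proto
}

type_faers_records <- function(raw, table_kind) {
  pid <- as.integer(raw$PRIMARYID)
  switch(table_kind,
    demo = tibble(
      primaryid = pid,
      caseid = as.integer(raw$CASEID),
      fda_dt = as.integer(raw$FDA_DT),
      sex = dplyr::case_match(toupper(raw$SEX %||% NA_character_),
                              "F" ~ "female", "M" ~ "male",
                              .default = NA_character_),
      age_years = convert_age(raw$AGE, raw$AGE_COD),
      country = raw$OCCR_COUNTRY,
      event_dt = if ("EVENT_DT" %in% names(raw)) raw$EVENT_DT
                 else NA_character_),
    drug = tibble(
      primaryid = pid,
      drug_seq = as.integer(raw$DRUG_SEQ),
      role_code = toupper(raw$ROLE_COD),
      name = toupper(raw$DRUGNAME),
      prod_ai = if ("PROD_AI" %in% names(raw)) toupper(raw$PROD_AI)
                else NA_character_),
    reac = tibble(primaryid = pid, pt = raw$PT),
    ther = tibble(primaryid = pid,
                  dsg_drug_seq = as.integer(raw$DSG_DRUG_SEQ),
                  start_dt = raw$START_DT),
    outc = tibble(primaryid = pid, outcome = code_to_outcome(toupper(raw$OUTC_COD))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert FAERS AGE / AGE_COD pairs to years
#'
#' Unit codes: DEC decades, YR years (default when the code is blank), MON
#' months, WK weeks, DY days, HR hours. Converted ages outside \[0, 130\]
#' years are set to missing with a warning (implausible entries such as an
#' age of 540 years occur in raw quarterly files).
#'
#' @param age numeric or character vector of age values.
#' @param age_cod character vector of unit codes.
#' @return numeric vector of ages in years (NA where missing/implausible).
#' @export
#' @examples
#' convert_age(c("45", "6"), c("YR", "MON"))
convert_age <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  factor <- dplyr::case_match(toupper(trimws(age_cod %||% "YR")),
                              "DEC" ~ 10, "YR" ~ 1, "MON" ~ 1 / 12,
                              "WK" ~ 7 / 365.25, "DY" ~ 1 / 365.25,
                              "HR" ~ 1 / 8766, .default = NA_real_)
  factor[is.na(age_cod) | trimws(age_cod) == ""] <- 1
  years <- age * factor
  bad <- !is.na(years) & (years < 0 | years > 130)
  if (any(bad)) {
    warn(sprintf("%d age value(s) outside [0, 130] years set to missing.",
                 sum(bad)))
    years[bad] <- NA_real_
  }
  years
}

#' Deduplicate report versions to one record per case
#'
#' FAERS distributes successive versions of the same safety report under a
#' shared CASEID. Following FDA guidance, the version with the largest
#' FDA_DT (latest receipt) is kept; ties on both CASEID and FDA_DT are
#' broken by the highest PRIMARYID. The operation is idempotent and
#' order-invariant; output is sorted by caseid.
#'
#' @param cases tibble with at least `primaryid`, `caseid`, `fda_dt`.
#' @return tibble with exactly one row per caseid.
#' @export
deduplicate_reports <- function(cases) {
  cases %>%
    arrange(.data$caseid, desc(.data$fda_dt), desc(.data$primaryid)) %>%
    distinct(.data$caseid, .keep_all = TRUE)
}

#' Select reports naming a target drug as suspect
#'
#' Matches drug mentions case-insensitively by substring against both the
#' drug name and the active-ingredient field. Under `"primary_suspect"`
#' (default) a report qualifies if any matching mention has role code PS.
#' Under `"sole_suspect"` the report must additionally have no
#' non-matching drug with role PS or SS.
#'
#' @param drugs tibble of drug mentions (`primaryid`, `role_code`, `name`,
#'   `prod_ai`).
#' @param name_list character vector of names to match (default the
#'   avacopan generic and brand names).
#' @param mode `"primary_suspect"` or `"sole_suspect"`.
#' @return integer vector of qualifying primaryids.
#' @export
select_target_reports <- function(drugs,
                                  name_list = c("AVACOPAN", "TAVNEOS"),
                                  mode = c("primary_suspect", "sole_suspect")) {
  if (length(name_list) == 0) {
    abort("`name_list` must be nonempty.", class = "faersignal_usage_error")
  }
  mode <- tryCatch(match.arg(mode), error = function(e) {
    abort(sprintf("Unknown mode '%s'; use primary_suspect or sole_suspect.",
                  paste(mode, collapse = "/")),
          class = "faersignal_usage_error")
  })
  pattern <- paste(sapply(toupper(name_list), rex_escape), collapse = "|")
  hit <- grepl(pattern, toupper(drugs$name)) |
    (!is.na(drugs$prod_ai) & grepl(pattern, toupper(drugs$prod_ai)))
  ps_ids <- unique(drugs$primaryid[hit & drugs$role_code == "PS"])
  if (mode == "sole_suspect") {
    other_suspect <- unique(
      drugs$primaryid[!hit & drugs$role_code %in% c("PS", "SS")])
    ps_ids <- setdiff(ps_ids, other_suspect)
  }
  sort(ps_ids)
}

rex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Read a preferred-term to system-organ-class mapping
#'
#' Two-column CSV (`pt`, `soc`). Each PT must map to exactly one SOC.
#'
#' @param path CSV path.
#' @return tibble with columns `pt`, `soc`.
#' @export
read_term_map <- function(path) {
  tm <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(tm) <- tolower(names(tm))
  if (!all(c("pt", "soc") %in% names(tm))) {
    abort("Term map must have columns 'pt' and 'soc'.",
          class = "faersignal_schema_error")
  }
  tm <- distinct(tm[, c("pt", "soc")])
  dup <- tm$pt[duplicated(tm$pt)]
  if (length(dup) > 0) {
    abort(sprintf("PT(s) mapped to multiple SOCs: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "faersignal_schema_error")
  }
  tm
}

#' Assemble the analysis dataset
#'
#' Deduplicates report versions, flags target-drug reports, joins events
#' and outcomes, and materializes the unique (report, PT) and (report, SOC)
#' incidence pairs that all disproportionality statistics count over. A
#' report contributes at most once per PT and once per SOC. Events whose PT
#' is absent from the term map are retained at PT level but excluded from
#' the SOC level (a message reports how many).
#'
#' @param demo,drugs,events typed record tibbles as returned by
#'   [read_faers_table()] (kinds demo, drug, reac).
#' @param term_map tibble (`pt`, `soc`) as from [read_term_map()].
#' @param outcomes,therapy optional typed outc / ther records.
#' @param target_names,mode passed to [select_target_reports()].
#' @return an object of class `faers_dataset`: list with `cases` (one row
#'   per deduplicated report, with `is_target`), `report_pt`, `report_soc`,
#'   `outcomes`, `onset` (target reports' raw start/event dates),
#'   `n_total`, `n_target`.
#' @export
build_dataset <- function(demo, drugs, events, term_map,
                          outcomes = NULL, therapy = NULL,
                          target_names = c("AVACOPAN", "TAVNEOS"),
                          mode = "primary_suspect") {
  cases <- deduplicate_reports(demo)
  target_ids <- select_target_reports(drugs, target_names, mode)
  cases <- mutate(cases, is_target = .data$primaryid %in% target_ids)
  if (!any(cases$is_target)) {
    abort("No target-drug reports after deduplication; cannot screen.",
          class = "faersignal_data_error")
  }
  keep <- cases$primaryid
  report_pt <- events %>%
    filter(.data$primaryid %in% keep, !is.na(.data$pt), .data$pt != "") %>%
    distinct(.data$primaryid, .data$pt)
  unmapped <- setdiff(unique(report_pt$pt), term_map$pt)
  if (length(unmapped) > 0) {
    inform(sprintf(
      "%d PT(s) absent from the term map; retained at PT level, excluded at SOC level.",
      length(unmapped)))
  }
  report_soc <- report_pt %>%
    inner_join(term_map, by = "pt") %>%
    distinct(.data$primaryid, .data$soc)
  out <- if (is.null(outcomes)) {
    tibble(primaryid = integer(), outcome = character())
  } else {
    distinct(filter(outcomes, .data$primaryid %in% keep))
  }
  onset <- build_onset_pairs(cases, drugs, therapy, target_names)
  structure(
    list(cases = arrange(cases, .data$caseid),
         report_pt = arrange(report_pt, .data$primaryid, .data$pt),
         report_soc = arrange(report_soc, .data$primaryid, .data$soc),
         outcomes = out,
         onset = onset,
         term_map = term_map,
         n_total = nrow(cases),
         n_target = sum(cases$is_target)),
    class = "faers_dataset")
}

# Raw (start_dt, event_dt) string pairs for target reports: the earliest
# therapy-start row of a matching suspect drug mention, the report's event
# date. Interval arithmetic and exclusions happen in onset_days().
build_onset_pairs <- function(cases, drugs, therapy, target_names) {
  target_cases <- filter(cases, .data$is_target)
  if (is.null(therapy)) {
    return(tibble(primaryid = target_cases$primaryid,
                  start_dt = NA_character_,
                  event_dt = target_cases$event_dt))
  }
  pattern <- paste(sapply(toupper(target_names), rex_escape), collapse = "|")
  tgt_drug <- drugs %>%
    filter(grepl(pattern, toupper(.data$name)) |
             (!is.na(.data$prod_ai) & grepl(pattern, toupper(.data$prod_ai))),
           .data$role_code == "PS") %>%
    select("primaryid", "drug_seq")
  starts <- therapy %>%
    inner_join(tgt_drug,
               by = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq")) %>%
    group_by(.data$primaryid) %>%
    summarise(start_dt = min_full_date(.data$start_dt), .groups = "drop")
  target_cases %>%
    select("primaryid", "event_dt") %>%
    left_join(starts, by = "primaryid") %>%
    select("primaryid", "start_dt", "event_dt")
}

# Earliest full-precision date string, else first non-missing raw value
# (kept so partial dates surface as partial, not missing).
min_full_date <- function(x) {
  full <- x[date_precision(x) == "full"]
  if (length(full) > 0) return(min(full))
  nonmiss <- x[!is.na(x) & x != ""]
  if (length(nonmiss) > 0) nonmiss[[1]] else NA_character_
}

#' Read a generated corpus directory back from disk
#'
#' Convenience wrapper: reads the five FAERS-dialect tables plus the PT
#' map written by [write_corpus()].
#'
#' @param dir directory containing `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `THER.txt`, `OUTC.txt`, `pt_soc_map.csv`.
#' @return list of typed record tibbles plus `term_map`.
#' @export
read_corpus_dir <- function(dir) {
  list(
    demo = read_faers_table(file.path(dir, "DEMO.txt"), "demo"),
    drug = read_faers_table(file.path(dir, "DRUG.txt"), "drug"),
    reac = read_faers_table(file.path(dir, "REAC.txt"), "reac"),
    ther = read_faers_table(file.path(dir, "THER.txt"), "ther"),
    outc = read_faers_table(file.path(dir, "OUTC.txt"), "outc"),
    term_map = read_term_map(file.path(dir, "pt_soc_map.csv"))
  )
}

#' Build the analysis dataset directly from an in-memory synthetic corpus
#'
#' @param corpus a `faers_corpus` from [generate_corpus()].
#' @param ... passed to [build_dataset()].
#' @return a `faers_dataset`.
#' @export
as_dataset <- function(corpus, ...) {
  build_dataset(corpus$demo, corpus$drug, corpus$reac, corpus$term_map,
                outcomes = corpus$outc, therapy = corpus$ther, ...)
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat(sprintf(
    "<faers_dataset> %d reports (%d target-drug), %d (report, PT) pairs, %d (report, SOC) pairs\n",
    x$n_total, x$n_target, nrow(x$report_pt), nrow(x$report_soc)))
  invisible(x)
}

#' @rdname glance.faers_screen
#' @export
glance.faers_dataset <- function(x, ...) {
  tibble(n_reports = x$n_total, n_target = x$n_target,
         n_pt = length(unique(x$report_pt$pt)),
         n_soc = length(unique(x$report_soc$soc)))
}
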