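# Parsing of the "$"-delimited dialect, age-unit conversion, deduplication,
# target selection and dataset assembly.

test_that("a DEMO row maps directly onto typed fields", {
  path <- withr::local_tempfile(lines = c(
    "PRIMARYID$CASEID$FDA_DT$SEX$AGE$AGE_COD$OCCR_COUNTRY$EVENT_DT",
    "100$7$20230301$F$45$YR$US$20230215",
    "101$8$20230302$M$6$MON$JP$202302",
    "102$9$20230303$$540$YR$$"))
  expect_warning(demo <- read_faers_table(path, "demo"), "130")
  expect_identical(demo$primaryid, c(100L, 101L, 102L))
  expect_identical(demo$sex, c("female", "male", NA))
  expect_equal(demo$age_years, c(45, 0.5, NA))
  expect_identical(demo$country, c("US", "JP", NA))
  expect_identical(demo$event_dt, c("20230215", "202302", NA))
})

test_that("age unit conversion follows FAERS codes and the plausibility guard", {
  expect_equal(convert_age(c("45", "6", "540", "7", "36"),
                           c("YR", "MON", "DY", "DEC", "MON")),
               c(45, 0.5, 540 / 365.25, 70, 3))
  expect_warning(out <- convert_age("540", "YR"), "outside")
  expect_true(is.na(out))
  expect_equal(convert_age("30", NA), 30)   # blank unit defaults to years
})

test_that("schema violations and empty files are reported", {
  bad <- withr::local_tempfile(lines = c("PRIMARYID$CASEID", "1$2"))
  expect_error(read_faers_table(bad, "demo"), "FDA_DT",
               class = "faersignal_schema_error")
  empty <- withr::local_tempfile(lines = character())
  expect_warning(out <- read_faers_table(empty, "reac"), "Empty")
  expect_identical(nrow(out), 0L)
  expect_error(read_faers_table(bad, "nonsense"),
               class = "faersignal_usage_error")
})

test_that("deduplication keeps max FDA_DT then max PRIMARYID, idempotently", {
  cases <- make_cases(primaryid = c(1, 2, 5, 9),
                      caseid = c(7, 7, 7, 8),
                      fda_dt = c(20230101, 20230301, 20230301, 20230601))
  out <- deduplicate_reports(cases)
  expect_identical(out$primaryid, c(5L, 9L))     # caseid 7: pid 5 wins tie
  expect_identical(out$fda_dt[out$caseid == 7L], 20230301L)
  # rule-forced survivor for a clean date difference
  two <- make_cases(primaryid = 1:2, caseid = 7,
                    fda_dt = c(20230101, 20230301))
  expect_identical(deduplicate_reports(two)$primaryid, 2L)
  # idempotence and identity on unique input
  expect_identical(deduplicate_reports(out), out)
})

test_that("deduplication is order-invariant", {
  set.seed(4)
  cases <- make_cases(primaryid = sample(1:50),
                      caseid = sample(1:20, 50, replace = TRUE),
                      fda_dt = 20230101L + sample(0:400, 50, replace = TRUE))
  ref <- deduplicate_reports(cases)
  for (i in 1:5) {
    shuffled <- cases[sample(nrow(cases)), ]
    expect_identical(deduplicate_reports(shuffled), ref)
  }
})

test_that("target selection honours role codes, name fields and modes", {
  drugs <- dplyr::bind_rows(
    make_drugs(1, "TAVNEOS", "PS"),
    make_drugs(1, "IBUPROFEN", "C", drug_seq = 2),
    make_drugs(2, "AVACOPAN", "PS"),
    make_drugs(2, "RITUXIMAB", "SS", drug_seq = 2),
    make_drugs(3, "AVACOPAN", "C"),
    make_drugs(4, "Tavneos 10mg", "PS"),
    make_drugs(5, "SOME BRAND", "PS", prod_ai = "AVACOPAN"))
  expect_identical(select_target_reports(drugs), c(1L, 2L, 4L, 5L))
  expect_identical(select_target_reports(drugs, mode = "sole_suspect"),
                   c(1L, 4L, 5L))
  expect_error(select_target_reports(drugs, mode = "both"),
               class = "faersignal_usage_error")
  expect_error(select_target_reports(drugs, name_list = character()),
               class = "faersignal_usage_error")
})

test_that("dataset assembly enforces unique (report, term) incidence", {
  demo <- make_cases(1:3)
  drugs <- make_drugs(1:3, c("AVACOPAN", "AVACOPAN", "OTHER"), "PS",
                      drug_seq = 1L)
  events <- make_events(c(1, 1, 2, 2, 3), c("Nausea", "Nausea", "PTa",
                                            "PTb", "PTa"))
  term_map <- tibble::tibble(pt = c("Nausea", "PTa", "PTb"),
                             soc = c("GI", "S2", "S2"))
  ds <- build_dataset(demo, drugs, events, term_map)
  expect_identical(sum(ds$report_pt$primaryid == 1), 1L)   # duplicate PT collapsed
  # two PTs of the same SOC give one (report, SOC) pair
  expect_identical(sum(ds$report_soc$primaryid == 2), 1L)
  expect_identical(ds$n_total, 3L)
  expect_identical(ds$n_target, 2L)
})

test_that("unmapped PTs stay at PT level but leave the SOC level", {
  demo <- make_cases(1:2)
  drugs <- make_drugs(1:2, c("AVACOPAN", "OTHER"), "PS", drug_seq = 1L)
  events <- make_events(c(1, 2), c("Mapped", "Orphan"))
  term_map <- tibble::tibble(pt = "Mapped", soc = "S1")
  expect_message(ds <- build_dataset(demo, drugs, events, term_map),
                 "1 PT")
  expect_true("Orphan" %in% ds$report_pt$pt)
  expect_false(any(ds$report_soc$primaryid == 2))
})

test_that("assembly fails loudly with zero target reports", {
  demo <- make_cases(1:2)
  drugs <- make_drugs(1:2, c("OTHER A", "OTHER B"), "PS", drug_seq = 1L)
  events <- make_events(1:2, c("X", "X"))
  expect_error(
    build_dataset(demo, drugs, events, tibble::tibble(pt = "X", soc = "S")),
    class = "faersignal_data_error")
})

test_that("a generated corpus survives the write/read round trip exactly", {
  cfg <- sim_config(n_reports = 800, duplicate_fraction = 0.1, seed = 21)
  corpus <- generate_corpus(cfg)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  back <- read_corpus_dir(dir)
  for (t in c("demo", "drug", "reac", "ther", "outc")) {
    expect_equal(as.data.frame(back[[t]]), as.data.frame(corpus[[t]]),
                 label = t)
  }
  expect_equal(as.data.frame(back$term_map),
               as.data.frame(corpus$term_map))
  # N after dedup equals the generator's distinct-case count
  ds <- build_dataset(back$demo, back$drug, back$reac, back$term_map)
  expect_identical(ds$n_total, length(unique(corpus$demo$caseid)))
})

test_that("per-PT target counts dominate the target report count", {
  ds <- as_dataset(generate_corpus(sim_config(n_reports = 4000, seed = 8)))
  target_ids <- ds$cases$primaryid[ds$cases$is_target]
  per_pt_sum <- sum(ds$report_pt$primaryid %in% target_ids)
  expect_gte(per_pt_sum, ds$n_target)
  # every (report, SOC) pair is implied by at least one (report, PT) pair
  implied <- dplyr::semi_join(ds$report_soc,
                              dplyr::inner_join(ds$report_pt, ds$term_map,
                                                by = "pt"),
                              by = c("primaryid", "soc"))
  expect_identical(nrow(implied), nrow(ds$report_soc))
})
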