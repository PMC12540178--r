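# The synthetic report generator: configuration validation, determinism,
# ground-truth convergence, referential integrity, duplicate injection.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_reports = 0), "n_reports",
               class = "faersignal_config_error")
  expect_error(sim_config(target_drug_share = 1), "target_drug_share",
               class = "faersignal_config_error")
  expect_error(sim_config(duplicate_fraction = 1), "duplicate_fraction",
               class = "faersignal_config_error")
  expect_error(sim_config(missing_sex_fraction = -0.1),
               "missing_sex_fraction", class = "faersignal_config_error")
  expect_error(sim_config(country_weights = c(US = 0)), "country_weights",
               class = "faersignal_config_error")
  expect_error(sim_config(signal_spec = c(PT9999 = 2), n_terms = 100),
               "PT9999", class = "faersignal_config_error")
  expect_error(sim_config(signal_spec = c(PT0001 = -1)), "signal_spec",
               class = "faersignal_config_error")
  expect_error(sim_config(onset_model = list(family = "weibull")),
               "onset_model", class = "faersignal_config_error")
})

test_that("identical configs give byte-identical output files", {
  cfg <- sim_config(n_reports = 1500, duplicate_fraction = 0.1, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(generate_corpus(cfg), d1)
  write_corpus(generate_corpus(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("generated tables are referentially intact", {
  corpus <- generate_corpus(sim_config(n_reports = 3000,
                                       duplicate_fraction = 0.1, seed = 9))
  expect_false(any(duplicated(corpus$demo$primaryid)))
  pids <- corpus$demo$primaryid
  expect_true(all(corpus$reac$primaryid %in% pids))
  expect_true(all(corpus$drug$primaryid %in% pids))
  expect_true(all(corpus$ther$primaryid %in% pids))
  expect_true(all(corpus$outc$primaryid %in% pids))
  # every case reports at least one PT and exactly one PS drug per version
  expect_true(all(pids %in% corpus$reac$primaryid))
  ps <- corpus$drug[corpus$drug$role_code == "PS", ]
  expect_identical(sort(unique(ps$primaryid)), sort(pids))
})

test_that("realized target-drug PT counts converge to the ground-truth expectation", {
  cfg <- sim_config(n_reports = 100000, target_drug_share = 0.5,
                    duplicate_fraction = 0, seed = 101)
  corpus <- generate_corpus(cfg)
  ds <- as_dataset(corpus)
  target_ids <- ds$cases$primaryid[ds$cases$is_target]
  realized <- dplyr::count(
    ds$report_pt[ds$report_pt$primaryid %in% target_ids, ], pt)
  gt <- merge(corpus$ground_truth, realized, by = "pt", all.x = TRUE)
  gt$n[is.na(gt$n)] <- 0L
  # standardized deviations from the binomial expectation stay bounded
  z <- (gt$n - gt$exp_a) / sqrt(pmax(gt$exp_a, 0.5))
  expect_lt(max(abs(z)), 4.5)
  # total realized pair count tracks the expectation closely
  expect_lt(abs(sum(gt$n) - sum(gt$exp_a)) / sum(gt$exp_a), 0.01)
  # where expected counts are large enough that a 5% band spans >= 4 SDs,
  # the relative error respects it
  big <- gt[gt$exp_a >= 6400, ]
  expect_gt(nrow(big), 0)
  expect_lt(max(abs(big$n - big$exp_a) / big$exp_a), 0.05)
})

test_that("expected cells are nonnegative and sum to the expected pair total", {
  cfg <- sim_config(n_reports = 10000, signal_spec = c(PT0003 = 4), seed = 2)
  gt <- sim_ground_truth(cfg)
  expect_true(all(gt[c("exp_a", "exp_b", "exp_c", "exp_d")] >= 0))
  expect_equal(unique(round(gt$exp_a + gt$exp_b + gt$exp_c + gt$exp_d, 9)),
               cfg$n_reports)
  expect_equal(gt$rate_ratio[gt$pt == "PT0003"], 4)
  # a rate-ratio-5 PT has true ROR close to (but not exactly) 5
  gt5 <- sim_ground_truth(sim_config(signal_spec = c(PT0028 = 5)))
  expect_gt(gt5$true_ror[gt5$pt == "PT0028"], 4.5)
  expect_lt(gt5$true_ror[gt5$pt == "PT0028"], 5.5)
})

test_that("duplicate injection creates CASEID-sharing versions with the forced survivors", {
  corpus <- generate_corpus(sim_config(n_reports = 400,
                                       duplicate_fraction = 0, seed = 3))
  expect_identical(inject_duplicates(corpus, 0), corpus)

  dup <- inject_duplicates(corpus, 0.25, seed = 7)
  expect_gt(nrow(dup$demo), length(unique(dup$demo$caseid)))
  expect_identical(sort(unique(dup$demo$caseid)), sort(corpus$demo$caseid))

  survivors <- deduplicate_reports(dup$demo)
  expect_identical(nrow(survivors), length(unique(dup$demo$caseid)))
  # survivor of each duplicated case is the latest FDA_DT, ties broken by
  # the highest PRIMARYID
  by_case <- split(dup$demo, dup$demo$caseid)
  multi <- by_case[vapply(by_case, nrow, 1L) > 1]
  expect_gt(length(multi), 0)
  for (versions in multi) {
    best <- versions[order(-versions$fda_dt, -versions$primaryid), ][1, ]
    expect_identical(
      survivors$primaryid[survivors$caseid == best$caseid], best$primaryid)
  }
  # duplicated content rows follow the new primaryids
  expect_true(all(dup$reac$primaryid %in% dup$demo$primaryid))
})

test_that("onset model produces the configured log-normal scale", {
  cfg <- sim_config(n_reports = 20000, missing_date_fraction = 0,
                    partial_date_fraction = 0, duplicate_fraction = 0,
                    seed = 12)
  corpus <- generate_corpus(cfg)
  od <- onset_days(corpus$demo$event_dt, corpus$ther$start_dt)
  med <- median(od$days, na.rm = TRUE)
  # median of the default log-normal is 87 days; 20k draws pin it tightly
  expect_gt(med, 78)
  expect_lt(med, 96)
})
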