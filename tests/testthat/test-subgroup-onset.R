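# Subgroup 2x2 tests and time-to-onset computation/summaries.

test_that("Pearson chi-square matches the closed-form expected counts", {
  out <- chi_square_2x2(matrix(c(10, 30, 90, 70), nrow = 2),
                        method = "pearson")
  # expected counts 20/80/20/80 give chi2 = 12.5
  expect_equal(out$chi2, 12.5)
  expect_lt(out$p, 0.001)

  flat <- chi_square_2x2(matrix(c(20, 20, 80, 80), nrow = 2),
                         method = "pearson")
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
})

test_that("auto mode falls back to Fisher below expected count 5", {
  small <- chi_square_2x2(matrix(c(1, 3, 2, 4), nrow = 2))
  expect_identical(small$method, "fisher")
  expect_true(is.na(small$chi2))
  big <- chi_square_2x2(matrix(c(10, 30, 90, 70), nrow = 2))
  expect_identical(big$method, "pearson")
  expect_error(chi_square_2x2(matrix(c(0, 5, 0, 5), nrow = 2)),
               class = "faersignal_stat_error")
})

test_that("the comparison is invariant under swapping the groups", {
  m <- matrix(c(12, 30, 88, 170), nrow = 2)
  swapped <- m[2:1, ]
  for (meth in c("pearson", "yates", "fisher")) {
    a <- chi_square_2x2(m, method = meth)
    b <- chi_square_2x2(swapped, method = meth)
    expect_equal(a$p, b$p)
    expect_equal(a$chi2, b$chi2)
  }
})

test_that("Fisher and Pearson agree on rejection for well-populated tables", {
  set.seed(77)
  agree <- 0; total <- 200
  for (i in seq_len(total)) {
    cells <- matrix(rpois(4, lambda = 80) + 20, nrow = 2)
    p_p <- chi_square_2x2(cells, method = "pearson")$p
    p_f <- chi_square_2x2(cells, method = "fisher")$p
    agree <- agree + ((p_p < 0.05) == (p_f < 0.05))
  }
  expect_gte(agree / total, 0.99)
})

test_that("subgroup comparison counts reports with any PT of the term set", {
  demo <- make_cases(1:8, country = rep(c("US", "JP"), each = 4))
  drugs <- make_drugs(1:8, "AVACOPAN", "PS", drug_seq = 1L)
  events <- make_events(c(1, 2, 3, 4, 5, 6, 7, 8),
                        c("Liv1", "Other", "Other", "Other", "Liv1",
                          "Liv2", "Liv1", "Other"))
  tm <- tibble::tibble(pt = c("Liv1", "Liv2", "Other"),
                       soc = c("Hep", "Hep", "Misc"))
  ds <- build_dataset(demo, drugs, events, tm)
  out <- compare_subgroups(ds, c("Liv1", "Liv2"), "country", "US", "JP",
                           method = "pearson")
  expect_identical(c(out$events_a, out$total_a, out$events_b, out$total_b),
                   c(1L, 4L, 3L, 4L))
  # saturated term set: both proportions 1, chi2 = 0
  sat <- compare_subgroups(ds, c("Liv1", "Liv2", "Other"), "country",
                           "US", "JP", method = "pearson")
  expect_identical(c(sat$events_a, sat$events_b), c(4L, 4L))
  expect_equal(sat$chi2, 0)
  expect_equal(sat$p, 1)
  expect_error(compare_subgroups(ds, "Liv1", "country", "US", "DE"),
               class = "faersignal_stat_error")
  # an empty group (zero row margin) is still an undefined comparison
  expect_error(chi_square_2x2(matrix(c(0, 5, 0, 5), nrow = 2)),
               class = "faersignal_stat_error")
})

test_that("onset intervals use full-precision dates only", {
  out <- onset_days(
    event_dt = c("20230131", "20230131", NA, "20230101", "202301"),
    start_dt = c("20230101", "202301", "20230101", "20230201", "20230101"))
  expect_identical(out$days, c(30L, NA, NA, NA, NA))
  expect_identical(out$reason,
                   c(NA, "partial_date", "missing", "negative",
                     "partial_date"))
})

test_that("onset summary uses linear-interpolation quantiles and half-open bins", {
  odd <- summarize_onset(c(10, 20, 30))
  expect_equal(odd$median, 20)

  s <- summarize_onset(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25)
  expect_lte(s$q1, s$median)
  expect_lte(s$median, s$q3)

  binned <- summarize_onset(c(5, 40, 400),
                            bin_edges = c(0, 30, 60, 90, 180, 360))
  expect_equal(binned$bins$proportion, c(1, 1, 0, 0, 0, 1) / 3)
  expect_equal(sum(binned$bins$proportion), 1, tolerance = 1e-9)
  expect_error(summarize_onset(integer()),
               class = "faersignal_data_error")
})

test_that("onset summary shifts with the data and ignores permutation", {
  set.seed(5)
  x <- sample(0:500, 40, replace = TRUE)
  s1 <- summarize_onset(x)
  s2 <- summarize_onset(sample(x))
  expect_equal(s1$median, s2$median)
  shifted <- summarize_onset(x + 17)
  expect_equal(shifted$median, s1$median + 17)
  expect_equal(shifted$q1, s1$q1 + 17)
  expect_equal(shifted$q3, s1$q3 + 17)
})

test_that("onset observations flow from the dataset with exclusion reasons", {
  cfg <- sim_config(n_reports = 5000, missing_date_fraction = 0.3,
                    partial_date_fraction = 0.1, seed = 13)
  ds <- as_dataset(generate_corpus(cfg))
  obs <- onset_observations(ds)
  expect_true(all(obs$days >= 0))
  excl <- attr(obs, "excluded")
  expect_true(sum(excl) + nrow(obs) == ds$n_target)
  expect_true("missing" %in% names(excl) || nrow(obs) == ds$n_target)
})
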