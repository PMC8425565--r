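test_that("diabetes needs two qualifying dates, mixable across criteria", {
  two_fpg <- mk_labs("FPG", c(130, 131), c("2009-01-05", "2009-03-05"))
  expect_equal(adjudicate_diabetes(two_fpg)$label, "true_case")

  mixed <- dplyr::bind_rows(
    mk_labs("HbA1c", 6.1, "2009-01-05"),
    mk_labs("FPG", 126, "2009-03-05"))
  expect_equal(adjudicate_diabetes(mixed)$label, "true_case")
  expect_equal(adjudicate_diabetes(mixed, mode = "per_criterion")$label,
               "other_case")

  once <- dplyr::bind_rows(
    mk_labs("FPG", 180, "2009-01-05"),
    mk_labs("HbA1c", 8.0, "2009-01-05"))  # same date counts once
  expect_equal(adjudicate_diabetes(once)$label, "other_case")

  expect_equal(adjudicate_diabetes(mk_labs("FPG", 125.9, "2009-01-05"))$label,
               "other_case")
})

test_that("dyslipidemia fires once, with a strict HDL boundary", {
  expect_equal(adjudicate_dyslipidemia(mk_labs("HDL", 39, "2009-01-05"))$label,
               "true_case")
  expect_equal(adjudicate_dyslipidemia(mk_labs("HDL", 40, "2009-01-05"))$label,
               "other_case")
  expect_equal(adjudicate_dyslipidemia(mk_labs("TG", 150, "2009-01-05"))$label,
               "true_case")
  none <- adjudicate_dyslipidemia(mk_labs("LDL", numeric(0), as.Date(character(0))))
  expect_equal(none$label, "other_case")
})

test_that("hyperthyroidism requires hormone excess plus suppressed TSH", {
  same_day <- dplyr::bind_rows(
    mk_labs("FT4", 2.0, "2009-01-05"),
    mk_labs("TSH", 0.05, "2009-01-05"))
  expect_equal(adjudicate_hyperthyroidism(same_day)$label, "true_case")

  normal_tsh <- dplyr::bind_rows(
    mk_labs("FT4", 2.0, "2009-01-05"),
    mk_labs("TSH", 2.5, "2009-01-05"))
  expect_equal(adjudicate_hyperthyroidism(normal_tsh)$label, "other_case")

  split_dates <- dplyr::bind_rows(
    mk_labs("FT4", 2.0, "2009-01-05"),
    mk_labs("TSH", 0.05, "2011-03-05"))
  expect_equal(adjudicate_hyperthyroidism(split_dates)$label, "other_case")
  expect_equal(adjudicate_hyperthyroidism(split_dates,
                                          simultaneity = "any_time")$label,
               "true_case")
})

test_that("observations with unexpected units are skipped with a warning", {
  bad <- mk_labs("FPG", 7.2, "2009-01-05")
  bad$unit <- "mmol/L"
  expect_warning(res <- adjudicate_diabetes(bad), "unexpected units")
  expect_equal(res$label, "other_case")
})

test_that("the creatinine rule ORs its absolute and ratio branches", {
  series <- function(values, dates) mk_labs("Cre", values, dates)
  # delta branch: 1.0 -> 1.31
  f <- detect_acute_cre_elevation(
    series(c(1.0, 1.31), c("2010-05-20", "2010-06-10")), "2010-06")
  expect_equal(f$absolute_delta, 0.31, tolerance = 1e-12)
  # ratio branch: 0.5 -> 0.76 (delta 0.26 misses, ratio 1.52 fires)
  f2 <- detect_acute_cre_elevation(
    series(c(0.5, 0.76), c("2010-05-20", "2010-06-10")), "2010-06")
  expect_equal(f2$ratio, 1.52, tolerance = 1e-12)
  # neither branch: 2.0 -> 2.25
  expect_null(detect_acute_cre_elevation(
    series(c(2.0, 2.25), c("2010-05-20", "2010-06-10")), "2010-06"))
  # no baseline in the three-month look-back
  expect_null(detect_acute_cre_elevation(
    series(c(1.0, 1.9), c("2009-12-20", "2010-06-10")), "2010-06"))
  expect_null(detect_acute_cre_elevation(series(numeric(0), character(0)),
                                         "2010-06"))
})

test_that("creatinine detector matches the exhaustive pairwise oracle", {
  set.seed(77)
  for (rep in 1:1000) {
    s <- random_cre_series(sample(2:10, 1))
    got <- detect_acute_cre_elevation(s, "2009-06")
    want <- oracle_cre(s$date, s$value, "2009-06")
    expect_equal(!is.null(got), !is.null(want), info = paste("rep", rep))
    if (!is.null(want)) {
      expect_equal(got$elevated_date, s$date[want$i])
      expect_equal(got$baseline_value, s$value[want$baseline])
    }
  }
})

test_that("prior-creatinine strata use closed boundaries as specified", {
  base_at <- function(b) mk_labs("Cre", c(b, b + 1), c("2010-05-20",
                                                       "2010-06-10"))
  expect_equal(stratify_prior_cre(base_at(1.2), "2010-06"), "<=1.2")
  expect_equal(stratify_prior_cre(base_at(1.21), "2010-06"), "(1.2,2.0]")
  expect_equal(stratify_prior_cre(base_at(2.0), "2010-06"), "(1.2,2.0]")
  expect_equal(stratify_prior_cre(base_at(2.5), "2010-06"), ">2.0")
  lone <- mk_labs("Cre", 1.0, "2010-06-10")
  expect_equal(stratify_prior_cre(lone, "2010-06"), "no_baseline")
  # stratum is assigned even when the rule does not fire
  flat <- mk_labs("Cre", c(1.5, 1.55), c("2010-05-20", "2010-06-10"))
  expect_equal(stratify_prior_cre(flat, "2010-06"), "(1.2,2.0]")
})

test_that("cohort adjudication partitions cases and matches scalar rules", {
  gen <- generate_cohort(cohort_config(n_patients = 150, seed = 31))
  cases <- extract_potential_cases(gen$cohort, default_code_lists())
  adj <- adjudicate_cohort(cases, gen$cohort, truth = gen$truth)
  expect_equal(nrow(adj), nrow(cases))
  expect_true(all(adj$label %in% c("true_case", "other_case")))
  expect_equal(sum(adj$label == "true_case") +
                 sum(adj$label == "other_case"), nrow(cases))

  # vectorized labels equal the per-patient reference rules
  m1 <- adj[adj$outcome != "acute_renal_failure", ]
  for (i in sample(nrow(m1), min(40, nrow(m1)))) {
    labs <- patient_timeline(gen$cohort, m1$patient_id[i])$labs
    ref <- switch(m1$outcome[i],
      diabetes = adjudicate_diabetes(labs),
      dyslipidemia = adjudicate_dyslipidemia(labs),
      hyperthyroidism = adjudicate_hyperthyroidism(labs))
    expect_equal(m1$label[i], ref$label,
                 info = paste(m1$outcome[i], m1$patient_id[i]))
  }

  expect_error(
    adjudicate_cohort(dplyr::mutate(cases[1, ], patient_id = "GHOST"),
                      gen$cohort),
    class = "phenovalid_data_error")
})

test_that("raising a threshold never increases the true-case count", {
  gen <- generate_cohort(cohort_config(n_patients = 200, seed = 13,
                                       outcomes = "diabetes"))
  cases <- extract_potential_cases(gen$cohort,
                                   default_code_lists()["diabetes"],
                                   def_ids = "D1", sources = "ssmix")
  b_at <- function(fpg, a1c) {
    th <- lab_rule_thresholds()
    th$fpg_ge <- fpg; th$hba1c_ge <- a1c
    adj <- adjudicate_cohort(cases, gen$cohort, thresholds = th)
    sum(adj$label == "true_case")
  }
  sweeps <- expand.grid(fpg = c(110, 126, 150, 200),
                        a1c = c(5.5, 6.1, 7.5))
  b <- mapply(b_at, sweeps$fpg, sweeps$a1c)
  for (a in unique(sweeps$a1c)) {
    expect_true(all(diff(b[sweeps$a1c == a]) <= 0))
  }
  for (f in unique(sweeps$fpg)) {
    expect_true(all(diff(b[sweeps$fpg == f]) <= 0))
  }
})
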