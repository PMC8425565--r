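codes <- test_codes()

test_that("first_event_month takes the earliest matching event", {
  tl <- mk_timeline(tibble::tibble(kind = c("dx", "dx"),
                                   month = c("2009-01", "2008-03")))
  expect_equal(first_event_month(tl, codes, "diagnosis"), "2008-03")
  expect_true(is.na(first_event_month(tl, codes, "prescription")))

  sus <- mk_timeline(tibble::tibble(kind = "dx", month = "2008-03",
                                    suspected = TRUE))
  expect_true(is.na(first_event_month(sus, codes, "diagnosis")))
  expect_equal(first_event_month(sus, codes, "diagnosis",
                                 definitive_only = FALSE), "2008-03")
})

test_that("interval-limited definitions fire at one month and not at two", {
  tl1 <- mk_timeline(tibble::tibble(kind = c("dx", "rx"),
                                    month = c("2009-04", "2009-05")))
  case <- evaluate_method1(tl1, "D3_2", codes)
  expect_equal(case$index_month, "2009-05")

  tl2 <- mk_timeline(tibble::tibble(kind = c("dx", "rx"),
                                    month = c("2009-04", "2009-06")))
  expect_null(evaluate_method1(tl2, "D3_2", codes))
  expect_equal(evaluate_method1(tl2, "D3_1", codes)$index_month, "2009-06")
})

test_that("practice-sequenced definitions respect the dx <= px <= rx order", {
  # practice after the prescription: the sequence is broken
  tl <- mk_timeline(tibble::tibble(kind = c("dx", "px", "rx"),
                                   month = c("2009-04", "2009-06",
                                             "2009-05")))
  expect_null(evaluate_method1(tl, "D6_1", codes))

  tl2 <- mk_timeline(tibble::tibble(kind = c("dx", "px", "rx"),
                                    month = c("2009-04", "2009-05",
                                              "2009-06")))
  expect_equal(evaluate_method1(tl2, "D6_1", codes)$index_month, "2009-06")
  expect_null(evaluate_method1(tl2, "D6_2", codes))  # dx->rx interval is 2

  # same-month collapse satisfies every "same as or before"
  tl3 <- mk_timeline(tibble::tibble(kind = c("dx", "px", "rx"),
                                    month = rep("2009-04", 3)))
  expect_equal(evaluate_method1(tl3, "D6_2", codes)$index_month, "2009-04")
})

test_that("index months follow the definition's index rule", {
  tl <- mk_timeline(tibble::tibble(kind = c("dx", "rx", "px"),
                                   month = c("2009-04", "2009-05",
                                             "2009-04")))
  expect_equal(evaluate_method1(tl, "D1", codes)$index_month, "2009-04")
  expect_equal(evaluate_method1(tl, "D2", codes)$index_month, "2009-05")
  expect_equal(evaluate_method1(tl, "D4", codes)$index_month, "2009-04")
  expect_equal(evaluate_method1(tl, "D3_1", codes)$index_month, "2009-05")
})

test_that("definition 5 modes: practice at prescription vs literal text", {
  tl <- mk_timeline(tibble::tibble(kind = c("dx", "px", "rx"),
                                   month = c("2009-04", "2009-04",
                                             "2009-06")))
  # practice coincides with the diagnosis, not the prescription
  expect_null(evaluate_method1(tl, "D5", codes))
  lit <- evaluate_method1(tl, "D5", codes,
                          options = extract_options(d5_literal = TRUE))
  expect_equal(lit$index_month, "2009-06")

  tl2 <- mk_timeline(tibble::tibble(kind = c("px", "rx"),
                                    month = c("2009-06", "2009-06")))
  expect_equal(evaluate_method1(tl2, "D5", codes)$index_month, "2009-06")
})

test_that("practice-based definitions reject the ssmix source", {
  tl <- mk_timeline(tibble::tibble(kind = "dx", month = "2009-04"),
                    source = "ssmix")
  expect_error(evaluate_method1(tl, "D4", codes, source = "ssmix"),
               class = "phenovalid_config_error")
  expect_error(evaluate_method1(tl, "D1", codes, source = "nonsense"),
               class = "phenovalid_config_error")
})

test_that("evaluate_method1 agrees with the brute-force oracle on random small timelines", {
  set.seed(101)
  months <- month_label(month_index("2009-01") + 0:5)
  for (rep in 1:300) {
    k <- sample(0:4, 1)
    ev <- tibble::tibble(
      kind = sample(c("dx", "rx", "px"), k, replace = TRUE),
      month = sample(months, k, replace = TRUE),
      suspected = sample(c(TRUE, FALSE), k, replace = TRUE))
    ev$suspected[ev$kind != "dx"] <- FALSE
    tl <- mk_timeline(ev)
    for (d in c("D1", "D2", "D3_1", "D3_2", "D4", "D5", "D6_1", "D6_2")) {
      want <- oracle_method1(d, ev)
      got <- evaluate_method1(tl, d, codes)
      expect_equal(!is.null(got), want$hit,
                   info = sprintf("def %s, events %s", d,
                                  paste(ev$kind, ev$month, collapse = ";")))
      if (want$hit) expect_equal(month_index(got$index_month), want$index)
    }
  }
})

test_that("the creatinine definition fires only near the index month", {
  w <- study_window("2008-01-01", "2011-12-31")
  arf <- code_list("acute_renal_failure",
                   tibble::tibble(icd10 = "N17", claim_code = "5847001"))
  base <- tibble::tibble(
    patient_id = "P1", month = "2010-06", icd10 = "N17",
    claim_code = "5847001", suspected = FALSE, source = "ssmix")
  tl <- function(lab_dates, values) {
    ehr_cohort(diagnoses = base,
               labs = mk_labs("Cre", values, lab_dates), window = w)
  }
  # rise of 0.35 within one month after diagnosis
  hit <- evaluate_method2(tl(c("2010-04-10", "2010-07-02"), c(1.0, 1.35)),
                          arf)
  expect_equal(hit$index_month, "2010-06")
  expect_equal(hit$cre_baseline, 1.0)
  expect_equal(hit$cre_elevated, 1.35)
  # same rise but two months late
  expect_null(evaluate_method2(tl(c("2010-07-10", "2010-09-02"),
                                  c(1.0, 1.35)), arf))
  # diagnosis without any creatinine data
  expect_null(evaluate_method2(ehr_cohort(diagnoses = base, window = w), arf))
})

test_that("extraction is deterministic, order-independent and matches per-patient evaluation", {
  gen <- generate_cohort(cohort_config(n_patients = 80, seed = 12,
                                       outcomes = "diabetes"))
  lists <- default_code_lists()["diabetes"]
  cases <- extract_potential_cases(gen$cohort, lists)

  shuffled <- gen$cohort
  set.seed(1)
  shuffled$diagnoses <- shuffled$diagnoses[
    sample(nrow(shuffled$diagnoses)), ]
  shuffled$prescriptions <- shuffled$prescriptions[
    sample(nrow(shuffled$prescriptions)), ]
  cases2 <- extract_potential_cases(shuffled, lists)
  expect_identical(cases, cases2)

  # at most one case per patient x definition x source
  expect_equal(anyDuplicated(cases[c("patient_id", "def_id", "source")]), 0L)

  # vectorized extraction equals the per-timeline evaluator
  all_ids <- cohort_patient_ids(gen$cohort)
  for (pid in sample(all_ids, min(25, length(all_ids)))) {
    tl <- patient_timeline(gen$cohort, pid)
    for (d in c("D1", "D3_2", "D6_1")) {
      got <- evaluate_method1(tl, d, lists$diabetes, source = "claims")
      in_cases <- any(cases$patient_id == pid & cases$def_id == d &
                        cases$source == "claims")
      expect_equal(!is.null(got), in_cases, info = paste(pid, d))
    }
  }
})
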