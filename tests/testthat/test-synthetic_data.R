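test_that("generation is deterministic under the seed and empty at n = 0", {
  g1 <- generate_cohort(cohort_config(n_patients = 50, seed = 8))
  g2 <- generate_cohort(cohort_config(n_patients = 50, seed = 8))
  expect_identical(g1$cohort$diagnoses, g2$cohort$diagnoses)
  expect_identical(g1$cohort$labs, g2$cohort$labs)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_cohort(cohort_config(n_patients = 50, seed = 9))
  expect_false(identical(g1$cohort$diagnoses, g3$cohort$diagnoses))

  g0 <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  expect_length(cohort_patient_ids(g0$cohort), 0L)
  expect_equal(nrow(g0$truth), 0L)
})

test_that("perfect coding and prevalence one force a 100% pipeline PPV", {
  cfg <- cohort_config(n_patients = 120, seed = 3, outcomes = "diabetes",
                       noise_scale = 0)
  cfg$outcomes$diabetes$prevalence <- 1
  cfg$outcomes$diabetes$sensitivity <- 1
  cfg$outcomes$diabetes$false_positive_rate <- 0
  gen <- generate_cohort(cfg)
  cases <- extract_potential_cases(gen$cohort,
                                   default_code_lists()["diabetes"],
                                   def_ids = "D1", sources = "ssmix")
  expect_equal(nrow(cases), 120L)
  adj <- adjudicate_cohort(cases, gen$cohort)
  expect_equal(sum(adj$label == "true_case"), 120L)
})

test_that("extraction recovers exactly the planted event structure", {
  gen <- generate_cohort(cohort_config(n_patients = 300, seed = 21,
                                       outcomes = "diabetes"))
  plan <- gen$plan
  cases <- extract_potential_cases(gen$cohort,
                                   default_code_lists()["diabetes"],
                                   sources = "claims")
  got <- function(d) sort(cases$patient_id[cases$def_id == d])
  # disease name only: exactly the patients given a definitive code
  expect_equal(got("D1"), sort(plan$patient_id[plan$coded]))
  # drug only: exactly the patients given a prescription
  expect_equal(got("D2"), sort(plan$patient_id[!is.na(plan$rx_month)]))
  # diagnosis then prescription: planted lags are always >= 0 months
  both <- plan$coded & !is.na(plan$rx_month)
  expect_equal(got("D3_1"), sort(plan$patient_id[both]))
  within1 <- both & !is.na(plan$dx_month) &
    month_index(ifelse(is.na(plan$rx_month), "2000-01", plan$rx_month)) -
    month_index(ifelse(is.na(plan$dx_month), "2000-01", plan$dx_month)) <= 1
  expect_equal(got("D3_2"), sort(plan$patient_id[within1]))
  # index months match the plan
  d1 <- cases[cases$def_id == "D1", ]
  expect_equal(d1$index_month,
               plan$dx_month[match(d1$patient_id, plan$patient_id)])
})

test_that("creatinine series construction guarantees the rule outcome", {
  cfg <- cohort_config(n_patients = 1, seed = 1)
  set.seed(55)
  for (stratum in c("<=1.2", "(1.2,2.0]", ">2.0")) {
    for (rep in 1:100) {
      s_case <- generate_arf_series(cfg, "2009-06", TRUE, stratum)
      expect_false(is.null(detect_acute_cre_elevation(s_case, "2009-06")))
      expect_equal(stratify_prior_cre(s_case, "2009-06"), stratum)
      s_non <- generate_arf_series(cfg, "2009-06", FALSE, stratum)
      expect_null(detect_acute_cre_elevation(s_non, "2009-06"))
    }
  }
})

test_that("adjudication reproduces ground-truth labels at default noise", {
  gen <- generate_cohort(cohort_config(n_patients = 600, seed = 17,
                                       outcomes = c("diabetes",
                                                    "dyslipidemia",
                                                    "hyperthyroidism")))
  # adjudicate every patient with any recorded event against every outcome
  # rule; patients with no events at all adjudicate trivially as other_case
  ids <- cohort_patient_ids(gen$cohort)
  agree <- numeric(0)
  for (oc in unique(gen$truth$outcome)) {
    fake_cases <- tibble::tibble(
      patient_id = ids, outcome = oc, def_id = "D1", source = "ssmix",
      index_month = "2009-01")
    adj <- adjudicate_cohort(fake_cases, gen$cohort)
    truth <- gen$truth[gen$truth$outcome == oc, ]
    lab <- adj$label[match(truth$patient_id, adj$patient_id)]
    lab[is.na(lab)] <- "other_case"
    agree <- c(agree, mean((lab == "true_case") == truth$is_case))
  }
  expect_true(all(agree >= 0.99))

  # and exactly with noise off
  gen0 <- generate_cohort(cohort_config(n_patients = 200, seed = 18,
                                        outcomes = "diabetes",
                                        noise_scale = 0))
  fake <- tibble::tibble(patient_id = cohort_patient_ids(gen0$cohort),
                         outcome = "diabetes", def_id = "D1",
                         source = "ssmix", index_month = "2009-01")
  adj0 <- adjudicate_cohort(fake, gen0$cohort)
  truth0 <- gen0$truth
  lab0 <- adj0$label[match(truth0$patient_id, adj0$patient_id)]
  lab0[is.na(lab0)] <- "other_case"
  expect_equal(mean((lab0 == "true_case") == truth0$is_case), 1)
})

test_that("both dialect serializations yield identical shared-source results", {
  gen <- generate_cohort(cohort_config(n_patients = 120, seed = 23,
                                       outcomes = c("diabetes",
                                                    "hyperthyroidism")))
  dir <- withr::local_tempdir()
  write_cohort_exports(gen, dir)
  claims <- read_claims_table(file.path(dir, "claims.csv"))
  store <- read_ssmix_store(file.path(dir, "store"))
  # carry the laboratory results over to the claims route: labs travel with
  # the EMR export regardless of which coded dialect is analysed
  claims$labs <- store$labs

  lists <- default_code_lists()[c("diabetes", "hyperthyroidism")]
  shared <- c("D1", "D2", "D3_1", "D3_2")
  from_claims <- extract_potential_cases(claims, lists, def_ids = shared,
                                         sources = "claims")
  from_store <- extract_potential_cases(store, lists, def_ids = shared,
                                        sources = "ssmix")
  key <- function(x) sort(paste(x$patient_id, x$outcome, x$def_id,
                                x$index_month))
  expect_equal(key(from_claims), key(from_store))

  adj_c <- adjudicate_cohort(from_claims, claims)
  adj_s <- adjudicate_cohort(from_store, store)
  expect_equal(sort(paste(adj_c$patient_id, adj_c$outcome, adj_c$def_id,
                          adj_c$label)),
               sort(paste(adj_s$patient_id, adj_s$outcome, adj_s$def_id,
                          adj_s$label)))
})

test_that("the false-positive rate back-solver inverts the coding model", {
  f <- solve_false_positive_rate(0.1, 0.95, 0.5)
  expect_equal(0.1 * 0.95 / (0.1 * 0.95 + 0.9 * f), 0.5, tolerance = 1e-9)
  expect_error(solve_false_positive_rate(0.5, 1, 0.3),
               class = "phenovalid_config_error")  # floor PPV is 0.5
  expect_error(solve_false_positive_rate(0.1, 0.95, 1),
               class = "phenovalid_config_error")
  cfg <- cohort_config(n_patients = 10, seed = 1, outcomes = "diabetes",
                       target_ppv = c(diabetes = 0.4))
  expect_equal(cfg$outcomes$diabetes$target_ppv, 0.4)
  expect_gt(cfg$outcomes$diabetes$false_positive_rate, 0)
})
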