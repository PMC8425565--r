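#!/usr/bin/env Rscript
# Adjudicate the potential cases and assemble the validation tables.
# Method-1 outcomes are adjudicated from laboratory thresholds; acute renal
# failure from a 30% random sample of potential cases, labelled by the
# ground truth standing in for medical-record review, and stratified by
# prior serum creatinine. Writes report.csv / report.txt and the
# per-stratum creatinine table.

suppressPackageStartupMessages({library(phenovalid); library(dplyr)})

claims <- read_claims_table("results/cohort/claims.csv")
store <- read_ssmix_store("results/cohort/store")
cohort <- ehr_cohort(
  diagnoses = bind_rows(claims$diagnoses, store$diagnoses),
  prescriptions = bind_rows(claims$prescriptions, store$prescriptions),
  practices = claims$practices, labs = store$labs)
truth <- readr::read_csv("results/cohort/ground_truth.csv",
                         show_col_types = FALSE)

res <- run_pipeline(run_config(
  cohort = cohort, truth = truth, seed = 20210908,
  sampling_fraction = 0.30, out_dir = "results/validation"))

cat("validation report (PPV with Wald 95% CI):\n")
writeLines(render_report(res$report))
cat("\nacute renal failure by prior-creatinine stratum:\n")
writeLines(render_report(res$report_arf_strata))
cat(sprintf("\nreviewed %d of %d creatinine potential cases (30%% sample)\n",
            nrow(res$subjects),
            sum(res$potential_cases$def_id == "M2_D1")))
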