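#!/usr/bin/env Rscript
# Read both serialized dialects back, pseudonymize, and apply every outcome
# definition: the eight Method-1 combinations of disease name / drug /
# medical practice for the three laboratory-adjudicated outcomes, and the
# disease-name + acute-creatinine definition for acute renal failure.
# Writes the potential-case table (count "A" per definition).

suppressPackageStartupMessages({library(phenovalid); library(dplyr)})

claims <- read_claims_table("results/cohort/claims.csv")
store <- read_ssmix_store("results/cohort/store")
cohort <- ehr_cohort(
  diagnoses = bind_rows(claims$diagnoses, store$diagnoses),
  prescriptions = bind_rows(claims$prescriptions, store$prescriptions),
  practices = claims$practices, labs = store$labs)

ps <- pseudonymize(cohort, mode = "escrow", seed = 20210908)
readr::write_csv(ps$key, "results/id_key.csv")  # "kept under lock and key"

cases <- extract_potential_cases(ps$cohort, default_code_lists())
readr::write_csv(cases, "results/potential_cases.csv")

cat("potential cases (A) per outcome / definition / source:\n")
print(count(cases, outcome, def_id, source), n = 40)
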