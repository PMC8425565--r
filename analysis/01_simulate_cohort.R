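#!/usr/bin/env Rscript
# Simulate the study's input data: a 2,000-patient cohort with known ground
# truth, serialized in both dialects a hospital would export — the monthly
# claims CSV and the SS-MIX2-style store — plus ground_truth.csv standing in
# for the medical-record review of acute renal failure.

suppressPackageStartupMessages(library(phenovalid))

out <- "results/cohort"
cfg <- cohort_config(n_patients = 2000, seed = 20210908)
gen <- generate_cohort(cfg)
write_cohort_exports(gen, out)

cat(sprintf("simulated %d patients into %s\n", cfg$n_patients, out))
cat(sprintf("  coded events: %d diagnoses, %d prescriptions, %d practice\n",
            nrow(gen$cohort$diagnoses), nrow(gen$cohort$prescriptions),
            nrow(gen$cohort$practices)))
cat(sprintf("  laboratory observations: %d\n", nrow(gen$cohort$labs)))
tt <- table(gen$truth$outcome[gen$truth$is_case])
for (oc in names(tt)) cat(sprintf("  true %s cases: %d\n", oc, tt[[oc]]))
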