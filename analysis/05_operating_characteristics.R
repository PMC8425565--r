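#!/usr/bin/env Rscript
# Operating characteristics of the pipeline on synthetic data:
#  (a) recovery of configured target PPVs (0.2 / 0.5 / 0.9) from
#      10,000-patient cohorts over 20 seeds each — the estimate should
#      bracket the target within its own Wald interval in ~19/20 runs;
#  (b) empirical coverage of the Wald interval at the study's sample sizes.

suppressPackageStartupMessages({library(phenovalid); library(dplyr)})

lists <- default_code_lists()["diabetes"]
rows <- list()
for (target in c(0.2, 0.5, 0.9)) {
  inside <- 0L; est <- numeric(20)
  for (s in 1:20) {
    cfg <- cohort_config(n_patients = 10000, seed = 30000 + s,
                         outcomes = "diabetes",
                         target_ppv = c(diabetes = target))
    gen <- generate_cohort(cfg)
    cases <- extract_potential_cases(gen$cohort, lists, def_ids = "D1",
                                     sources = "ssmix")
    adj <- adjudicate_cohort(cases, gen$cohort)
    B <- sum(adj$label == "true_case")
    est[s] <- 100 * B / nrow(adj)
    ci <- wald_ci(B, nrow(adj))
    inside <- inside + (ci$ci_low_pct <= 100 * target &&
                          100 * target <= ci$ci_high_pct)
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    target_ppv_pct = 100 * target, mean_estimate_pct = mean(est),
    sd_estimate_pct = sd(est), runs_inside_ci = inside, runs = 20L)
  cat(sprintf("target %.0f%%: mean estimate %.2f%%, %d/20 runs bracket the target\n",
              100 * target, mean(est), inside))
}
recovery <- bind_rows(rows)
readr::write_csv(recovery, "results/ppv_recovery.csv")

set.seed(20210908)
cov <- list()
for (p in c(0.2, 0.5, 0.9)) {
  for (n in c(162, 432, 5000)) {
    b <- rbinom(5000, n, p)
    ci <- wald_ci(b, rep(n, 5000))
    cov[[length(cov) + 1L]] <- tibble::tibble(
      p = p, n = n,
      coverage = mean(ci$ci_low_pct <= 100 * p & 100 * p <= ci$ci_high_pct))
  }
}
coverage <- bind_rows(cov)
readr::write_csv(coverage, "results/wald_coverage.csv")
cat("\nWald 95% interval empirical coverage (5,000 replicates):\n")
print(coverage, n = 9)
cat("undercoverage at extreme p with small n is the known behaviour of the\nWald interval, not an implementation defect\n")
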