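# phenovalid

Validation of coded outcome definitions in claims and EMR export data.

Before routinely collected hospital data — monthly insurance-claims
extracts and standardized EMR exports (SS-MIX2-style storage) — can be used
for pharmacovigilance, the *outcome definitions* that flag new-onset cases
from coded diagnoses, drugs and medical-practice items must be validated.
phenovalid implements that validation pipeline for four study outcomes
(diabetes, dyslipidemia, hyperthyroidism, acute renal failure):

* **records_io** — readers/writers for a monthly claims CSV dialect, a
  simplified SS-MIX2-style store, and code-list CSVs; patient-ID
  pseudonymization with or without a key table.
* **outcome engine** — nine declarative definitions with month-level
  temporal logic (e.g. *initial definitive diagnosis in the same month as
  or before the initial prescription, at most 1 month apart*), each
  assigning an index month; the acute-renal-failure definition couples the
  diagnosis to an acute serum-creatinine elevation.
* **adjudication** — rule-based true-case classification: laboratory
  thresholds (FPG ≥ 126 mg/dL twice, HDL < 40 mg/dL once, FT4 ≥ 1.8 ng/dL
  with TSH ≤ 0.1 uU/mL, …) and the creatinine rule (rise ≥ 0.3 mg/dL or to
  ≥ 150 % of the most recent value of the prior 3 months), with
  prior-creatinine strata ≤ 1.2 / (1.2, 2.0] / > 2.0 mg/dL.
* **validity** — PPV% = 100·B/n with Wald 95 % confidence intervals
  `100(p ± 1.96√(p(1−p)/n))`, 30 % random-sample review for record-based
  adjudication, and table assembly/rendering.
* **synthetic data** — cohorts with known ground truth in both dialects,
  with configurable prevalence, coding error rates, lags and lab
  distributions; target PPVs are hit by back-solving the false-positive
  coding rate.

The methods vignette
(`vignettes/phenotype-validation-methods.Rmd`) documents the rules, the
open protocol points and how each was decided.

## Worked example

```r
library(phenovalid)

gen <- generate_cohort(cohort_config(n_patients = 500, seed = 7))
res <- run_pipeline(run_config(cohort = gen$cohort, truth = gen$truth,
                               seed = 3))
writeLines(render_report(res$report)[1:4])
#> Definition                                           Potential  Subjects     True    Other  PPV (95% CI)
#> diabetes / D1 / claims                                      76        76       48       28  63.2% (52.3-74.0)
#> diabetes / D1 / ssmix                                       76        76       48       28  63.2% (52.3-74.0)
#> diabetes / D2 / claims                                      52        52       43        9  82.7% (72.4-93.0)
```

Reading: of 76 patients flagged by the disease-name-only definition (D1),
48 were confirmed by the laboratory rules, a PPV of 63.2 % with Wald 95 %
CI 52.3–74.0 %. Narrower definitions trade potential cases (A) for PPV —
the structure the validation is designed to expose.

The published count tables ship with the package and recompute through the
same arithmetic:

```r
format_ppv(4646, 22086)
#> [1] "21.0% (20.5-21.6)"
```

## Analysis workflow

`analysis/` holds the numbered drivers of the full study, writing tables
under `results/`:

1. `01_simulate_cohort.R` — 2,000-patient cohort, both dialects + truth
2. `02_extract_cases.R` — pseudonymize and extract potential cases
3. `03_adjudicate_validate.R` — adjudicate, 30 % sample for acute renal
   failure, PPV tables incl. prior-creatinine strata
4. `04_published_arithmetic.R` — recompute all 40 published PPV/CI cells
5. `05_operating_characteristics.R` — target-PPV recovery and Wald
   coverage

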