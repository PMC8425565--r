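---
title: "Validating coded outcome definitions: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating coded outcome definitions: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenovalid)
```

## The problem

Pharmacovigilance increasingly relies on secondary use of routinely
collected hospital data: monthly insurance-claims extracts and standardized
EMR exports (in Japan, SS-MIX2 standardized storage). Before such data can
be used to monitor adverse drug events, the *outcome definitions* — rules
that flag a patient as a new-onset case from coded diagnoses, drug
prescriptions and medical-practice items — must be validated. The standard
yardstick is the positive predictive value (PPV): of the patients a
definition flags ("potential cases", count $A$), what fraction are real
("true cases", count $B$), as judged by an independent adjudication?

phenovalid implements that validation pipeline end to end for four study
outcomes — new-onset diabetes, dyslipidemia, hyperthyroidism and acute
renal failure — together with a synthetic cohort generator so every step
can be exercised against known ground truth.

## Data model

Claims data carry coded events at calendar-month granularity, so all
temporal logic runs on month indices ($12 \times \text{year} + \text{month}$);
EMR-export events carry dates and are reduced to months for the outcome
engine, while laboratory observations keep full dates. Practice codes exist
only in claims extracts and laboratory results only in the EMR export, which
is why four of the nine definitions are claims-only and the creatinine
definition is export-only. The simplified store layout used here
(`root/<patient>/<YYYY-MM>/{DG1,RXE,OBX}.txt`, pipe-delimited) is a
deliberately reduced line grammar inspired by the HL7 v2.5 segments of the
real export; it is *not* conformant HL7, and parsing real SS-MIX2 storage is
out of scope.

Patient identifiers are replaced by second study IDs before analysis
(`pseudonymize()`); in irreversible mode the correspondence table is
discarded, in escrow mode it is returned so record-based adjudication can
re-consult source data — mirroring how the two validation methods handled
anonymization in practice.

## Outcome definitions

`outcome_definitions()` lists the nine rules. For the three
laboratory-adjudicated outcomes, the eight Method-1 definitions combine the
initial definitive diagnosis month $d$, the initial prescription month $r$
and practice months $p$:

| id | components | predicate | index month |
|------|---------------------|---------------------------------|------|
| D1 | disease name | $d$ exists | $d$ |
| D2 | drug | $r$ exists | $r$ |
| D3-1 | disease + drug | $d \le r$ | $r$ |
| D3-2 | disease + drug | $d \le r \le d + 1$ | $r$ |
| D4 | disease + practice | $\exists p : p = d$ | $d$ |
| D5 | drug + practice | $\exists p : p = r$ | $r$ |
| D6-1 | disease + practice + drug | $\exists p : d \le p \le r$ | $r$ |
| D6-2 | as D6-1 | and $r \le d + 1$ | $r$ |

"Definitive" means the claim's suspected-diagnosis flag is unset; whether
suspected diagnoses should anchor a definition is not knowable from the
published protocol, so `extract_options(definitive_only = FALSE)` exposes
the alternative. Months are unordered within themselves: a diagnosis and a
prescription in the same month satisfy "same as or prior to" regardless of
day order, which month-granular claims cannot resolve. "One month or
shorter" is the month-index difference $r - d \in \{0, 1\}$.

Two open points were decided as follows:

* **Definition 5.** Its published temporal sentence repeats Definition 4's
  ("diagnosis month equals practice month") although the definition uses
  drug and practice data only. We implement the predicate the data sources
  imply — practice month equals the initial prescription month — and keep
  the literal sentence behind `extract_options(d5_literal = TRUE)`.
* **Washout.** New onset is defined as first occurrence within the
  observation window (2007-04-01 to 2011-12-31 by default); no additional
  look-back washout is imposed, but `washout_months` exists for sensitivity
  analyses.

The acute-renal-failure definition (`M2_D1`) fires when the initial
definitive diagnosis month $m$ is accompanied by an acute serum-creatinine
elevation dated within months $[m-1, m+1]$.

## Adjudication rules

Method-1 outcomes are adjudicated from laboratory results alone:

* **diabetes** — fasting glucose $\ge$ 126 mg/dL or casual glucose $\ge$
  200 mg/dL or HbA1c $\ge$ 6.1 % on **two or more distinct dates**. The
  6.1 % cut-off is the JDS-era value used by the original protocol and is
  kept verbatim (no NGSP conversion). The protocol does not say whether the
  same criterion must repeat; the default lets the two dates come from
  different criteria, with a stricter `per_criterion` mode available.
* **dyslipidemia** — LDL $\ge$ 140, HDL $<$ 40 (strict) or TG $\ge$ 150
  mg/dL **at least once**.
* **hyperthyroidism** — elevated free hormone (FT4 $\ge$ 1.8 ng/dL or FT3
  $\ge$ 4.0 pg/mL) **and** suppressed TSH $\le$ 0.1 uU/mL. A thyroid panel
  is normally one blood draw, so the default requires both criteria on the
  same date; `simultaneity = "any_time"` accepts them anywhere in the
  period. (FT3 is thresholded in pg/mL, the unit in which free T3 is
  clinically reported and in which 4.0 is an upper reference bound.)

The acute creatinine rule (`detect_acute_cre_elevation()`) scans
observations within one month of the index month for a value that exceeds
its baseline by $\ge$ 0.3 mg/dL or reaches $\ge$ 150 % of it ("up to 150 %"
is read as ratio $\ge 1.5$, inclusive). The baseline is *the previous serum
creatinine of the past 3 months*: the phrase is singular, so the default
statistic is the most recent prior value (observations earlier in the same
calendar month count as prior; date ties are resolved by input order);
`min` and `mean` are available as alternatives. A zero baseline disables
the ratio branch only. Patients with no baseline cannot qualify and are
reported as `no_baseline` by the stratifier.

Prior-creatinine strata ($\le 1.2$, $(1.2, 2.0]$, $> 2.0$ mg/dL, closed
upper bounds) screen out chronically elevated patients (long-term dialysis,
transplantation). The published stratum table has overlapping boundary
typography and stratum counts that exceed the overall potential-case count;
we report disjoint strata as the methods text defines them rather than
reproduce that overlap.

Record review for acute renal failure cannot be re-run from coded data, so
`adjudicate_cohort()` accepts a ground-truth table (from the generator) as
its stand-in; without one, the creatinine rule itself is the oracle — which
every extracted case satisfies by construction, so supplying truth is what
makes stratum-level PPVs informative on synthetic data.

## Validity statistics

$\mathrm{PPV\%} = 100\,B/n$, where $n$ is the number adjudicated: all
potential cases for laboratory adjudication, or the reviewed random sample
for record-based adjudication (`sample_subjects()` draws
$\mathrm{round\_half\_up}(0.30\,N)$ without replacement; the original study
reports 432 of 1,447 — 29.85 %, an unstated rounding we do not attempt to
reproduce). The 95 % interval is Wald,
$100\,(p \pm 1.96\sqrt{p(1-p)/n})$, clamped to $[0,100]$ — deliberately so,
with no continuity correction and no Wilson/Agresti–Coull substitute,
because Wald is the method under validation. Its undercoverage at extreme
$p$ with small $n$ is expected behaviour (see
`analysis/05_operating_characteristics.R`). Display rounding is half-up to
one decimal; this combination reproduces all 40 published PPV/CI cells
exactly from their count pairs:

```{r}
head(validate_from_counts(printed_validation_counts())[
  c("outcome", "def_id", "source", "ppv_display")], 4)
```

## What the synthetic generator emulates

`generate_cohort()` draws, per outcome: disease status at the configured
prevalence; coded diagnoses with sensitivity 0.95 for cases and a
false-positive coding rate for non-cases (defaults in
`inst/extdata/default_cohort_config.yaml`); an optional extra
suspected-only diagnosis (rate 0.05) that definitive-only extraction must
ignore; prescriptions lagging the diagnosis by 0–2 months
(probabilities 0.6/0.3/0.1) and practice items by 0–1 months; and
laboratory panels from truncated-normal case / non-case distributions whose
means sit firmly on the correct side of each adjudication threshold (e.g.
case fasting glucose 160 ± 25 vs non-case 95 ± 10 mg/dL). With the default
noise the laboratory rules reproduce ground-truth labels for over 99 % of
patients, and exactly when `noise_scale = 0`.

Creatinine series are built by `generate_arf_series()`: two baseline values
inside the requested stratum in the three months before the index month,
then follow-ups that either contain a planted rise of $\ge$ 0.35 mg/dL
(rule fires by construction) or fluctuate within $[-0.08, +0.12]$ mg/dL of
baseline — bounds chosen so that for any admissible baseline
($\ge 0.6$ mg/dL) neither the absolute nor the ratio branch can fire. A
configurable fraction of coded non-cases receives a *rule-firing* series
with a ground-truth label of non-case (rising with stratum: 0.10 / 0.25 /
0.80), emulating the chronic and acute-on-chronic elevations that record
review rejects; this is what gives the synthetic stratum table its
published-like PPV gradient.

When a `target_ppv` is requested, the expected disease-name-only PPV
$\pi s / (\pi s + (1-\pi) f)$ is inverted for the false-positive coding
rate $f$ by bisection (the map is monotone), holding prevalence $\pi$ and
sensitivity $s$ fixed. All randomness flows from one master seed through
named substreams (coding, lags, labs, dates), so each component is
independently reproducible and the package never perturbs the caller's RNG
state.

What the generator does **not** emulate: realistic billing structure and
visit patterns, drug dosing, repeat disease episodes, between-source
disagreement (claims and export carry identical clinical content, which is
also what makes the dialect-equivalence tests sharp), and secular trends in
coding. Passing tests on synthetic cohorts therefore demonstrate that the
machinery is correct under the stated model, not that the published
hospital-level counts — which would require the six hospitals' data — are
reproducible.

## Numerical and testing choices

Tests enumerate all event multisets of size ≤ 4 over a six-month grid
(~20,000 timelines) and check every Method-1 predicate against an
independently coded nested-conditional oracle; the creatinine rule is
checked against an exhaustive pairwise scan on 10,000 random series (drawn
with distinct dates, since equal-dated baselines make "most recent"
ambiguous). Parameter recovery uses 10,000-patient cohorts, 20 seeds per
target PPV ∈ {0.2, 0.5, 0.9}; the analysis scripts use a 2,000-patient
cohort and 5,000 binomial replicates for coverage — sizes chosen to keep
each script in the seconds-to-minutes range while leaving Monte-Carlo error
well inside the assertion margins.

## Known limitations

* Repeat episodes are out of scope: one potential case per patient,
  outcome, definition and source.
* Sensitivity, specificity and NPV are not computable — the design
  adjudicates flagged patients only.
* ICD-10 codes are validated by shape (`[A-Z][0-9]{2}`), not against the
  official classification; code lists beyond the few public examples are
  synthetic stand-ins.
* Incidence estimation, exposure risk windows and disproportionality
  statistics are non-goals; the package validates definitions, nothing
  downstream of them.
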