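# Default synthetic-cohort parameters.
#
# The generator emulates the statistical structure a claims/EMR validation
# study assumes: per-outcome disease prevalence, imperfect coding (a case is
# coded with `sensitivity`; a non-case attracts the code at
# `false_positive_rate`), treatment/practice events lagging the initial
# diagnosis by whole months, and laboratory values drawn from separate
# case / non-case distributions (truncated normals; means/sds chosen as
# clinically plausible for each analyte's canonical unit).
#
# lag_rx_probs: P(initial prescription lags the initial diagnosis by 0,1,2 months)
# lag_px_probs: P(practice item lags the diagnosis month by 0,1 months)
# Each laboratory entry is [mean, sd]; a "panel" is one blood draw on one
# date carrying all of the outcome's analytes. n_panels_* counts draws per
# patient over the observation period.

suspected_extra_rate: 0.05
lag_rx_probs: [0.60, 0.30, 0.10]
lag_px_probs: [0.85, 0.15]

outcomes:
  diabetes:
    prevalence: 0.10
    sensitivity: 0.95
    false_positive_rate: 0.08
    rx_given_case: 0.85
    rx_given_noncase: 0.35
    rx_alone_case: 0.05
    rx_alone_noncase: 0.002
    px_given_dx: 0.80
    px_at_rx: 0.60
    n_panels_case: 4
    n_panels_noncase: 2
    labs:
      case:    {FPG: [160, 25], casual_glucose: [230, 40], HbA1c: [8.0, 1.2]}
      noncase: {FPG: [95, 10],  casual_glucose: [110, 20], HbA1c: [5.4, 0.3]}
  dyslipidemia:
    prevalence: 0.15
    sensitivity: 0.95
    false_positive_rate: 0.06
    rx_given_case: 0.75
    rx_given_noncase: 0.30
    rx_alone_case: 0.05
    rx_alone_noncase: 0.002
    px_given_dx: 0.80
    px_at_rx: 0.60
    n_panels_case: 2
    n_panels_noncase: 2
    labs:
      case:    {LDL: [175, 20], HDL: [48, 6], TG: [210, 50]}
      noncase: {LDL: [100, 12], HDL: [58, 5], TG: [90, 20]}
  hyperthyroidism:
    prevalence: 0.02
    sensitivity: 0.95
    false_positive_rate: 0.01
    rx_given_case: 0.80
    rx_given_noncase: 0.15
    rx_alone_case: 0.03
    rx_alone_noncase: 0.001
    px_given_dx: 0.80
    px_at_rx: 0.60
    n_panels_case: 2
    n_panels_noncase: 2
    labs:
      case:    {FT4: [3.0, 0.6], FT3: [5.5, 1.0], TSH: [0.02, 0.03]}
      noncase: {FT4: [1.2, 0.2], FT3: [2.8, 0.5], TSH: [1.8, 0.6]}
  acute_renal_failure:
    prevalence: 0.03
    sensitivity: 0.90
    false_positive_rate: 0.02
    cre_tested_noncase: 0.90
    # fraction of coded patients whose creatinine series satisfies the acute
    # elevation rule although record review (ground truth) rejects them --
    # chronic / acute-on-chronic elevations; rises with the prior-Cre stratum
    rule_positive_noncase:
      "<=1.2": 0.10
      "(1.2,2.0]": 0.25
      ">2.0": 0.80
    # prior-Cre stratum mix among rule-firing patients
    stratum_probs_case:    [0.50, 0.40, 0.10]
    stratum_probs_noncase: [0.15, 0.25, 0.60]
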