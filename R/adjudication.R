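#' Laboratory rule thresholds
#'
#' The case-identification thresholds used to adjudicate potential cases:
#' diabetes requires fasting glucose >= 126 mg/dL or casual glucose >= 200
#' mg/dL or HbA1c >= 6.1% (the era's JDS-aligned cut-off, kept verbatim — no
#' NGSP conversion is applied) on two or more distinct dates; dyslipidemia
#' requires LDL >= 140, HDL < 40 or TG >= 150 mg/dL at least once;
#' hyperthyroidism requires an elevated free hormone (FT4 >= 1.8 ng/dL or
#' FT3 >= 4.0 pg/mL) together with suppressed TSH <= 0.1 uU/mL. The acute
#' creatinine rule fires on a rise of >= 0.3 mg/dL or to >= 150% of
#' baseline.
#'
#' @return A named list of numeric thresholds; pass a modified copy to the
#'   `adjudicate_*` functions to study threshold sensitivity.
#' @export
lab_rule_thresholds <- function() {
  list(
    fpg_ge = 126, casual_glucose_ge = 200, hba1c_ge = 6.1,
    ldl_ge = 140, hdl_lt = 40, tg_ge = 150,
    ft4_ge = 1.8, ft3_ge = 4.0, tsh_le = 0.1,
    cre_delta_ge = 0.3, cre_ratio_ge = 1.5
  )
}

# drop observations whose unit does not match the canonical unit table;
# warn once with a count
check_units <- function(labs) {
  if (!nrow(labs)) return(labs)
  expected <- lab_unit_table()[labs$item]
  ok <- is.na(expected) | labs$unit == expected
  if (any(!ok)) {
    warning(sprintf("skipping %d lab observation(s) with unexpected units",
                    sum(!ok)), call. = FALSE)
  }
  labs[ok, , drop = FALSE]
}

adjudication_row <- function(patient_id, outcome, label, evidence_dates,
                             stratum = NA_character_) {
  tibble::tibble(
    patient_id = patient_id, outcome = outcome, label = label,
    n_evidence = length(evidence_dates),
    evidence_dates = paste(sort(unique(as.character(evidence_dates))),
                           collapse = ";"),
    stratum = stratum
  )
}

#' Adjudicate diabetes from laboratory results
#'
#' A patient is a true case when the glucose criterion (fasting glucose
#' >= 126 mg/dL or casual glucose >= 200 mg/dL) or the HbA1c criterion
#' (>= 6.1%) is met on at least two distinct dates during the observation
#' period. With `mode = "mixed"` (default) the two qualifying dates may come
#' from different criteria; `mode = "per_criterion"` requires a single
#' criterion to repeat.
#'
#' @param labs One patient's laboratory observations (tibble with `date`,
#'   `item`, `value`, `unit`).
#' @param mode Qualifying-date combination rule; see Details.
#' @param thresholds See [lab_rule_thresholds()].
#' @return A one-row tibble with `label` (`"true_case"`/`"other_case"`) and
#'   the qualifying dates as evidence.
#' @export
adjudicate_diabetes <- function(labs, mode = c("mixed", "per_criterion"),
                                thresholds = lab_rule_thresholds()) {
  mode <- match.arg(mode)
  labs <- check_units(labs)
  glu <- labs$date[(labs$item == "FPG" & labs$value >= thresholds$fpg_ge) |
                     (labs$item == "casual_glucose" &
                        labs$value >= thresholds$casual_glucose_ge)]
  a1c <- labs$date[labs$item == "HbA1c" & labs$value >= thresholds$hba1c_ge]
  hit <- if (mode == "mixed") {
    length(unique(c(glu, a1c))) >= 2L
  } else {
    length(unique(glu)) >= 2L || length(unique(a1c)) >= 2L
  }
  adjudication_row(one_patient_id(labs), "diabetes",
                   if (hit) "true_case" else "other_case",
                   if (hit) unique(c(glu, a1c)) else as.Date(character()))
}

#' Adjudicate dyslipidemia from laboratory results
#'
#' True case when LDL cholesterol >= 140 mg/dL, HDL cholesterol < 40 mg/dL
#' (strictly below), or triglycerides >= 150 mg/dL on at least one date.
#'
#' @inheritParams adjudicate_diabetes
#' @return A one-row tibble as for [adjudicate_diabetes()].
#' @export
adjudicate_dyslipidemia <- function(labs,
                                    thresholds = lab_rule_thresholds()) {
  labs <- check_units(labs)
  hit_dates <- labs$date[
    (labs$item == "LDL" & labs$value >= thresholds$ldl_ge) |
      (labs$item == "HDL" & labs$value < thresholds$hdl_lt) |
      (labs$item == "TG" & labs$value >= thresholds$tg_ge)]
  hit <- length(hit_dates) >= 1L
  adjudication_row(one_patient_id(labs), "dyslipidemia",
                   if (hit) "true_case" else "other_case",
                   if (hit) hit_dates else as.Date(character()))
}

#' Adjudicate hyperthyroidism from laboratory results
#'
#' True case when both criteria hold: an elevated free thyroid hormone
#' (FT4 >= 1.8 ng/dL or FT3 >= 4.0 pg/mL) and a suppressed TSH
#' (<= 0.1 uU/mL). By default both must be satisfied on the same date — a
#' thyroid panel is normally drawn as one sample — while
#' `simultaneity = "any_time"` accepts the two criteria on different dates
#' anywhere in the observation period.
#'
#' @inheritParams adjudicate_diabetes
#' @param simultaneity `"same_date"` (default) or `"any_time"`.
#' @return A one-row tibble as for [adjudicate_diabetes()].
#' @export
adjudicate_hyperthyroidism <- function(labs,
                                       simultaneity = c("same_date",
                                                        "any_time"),
                                       thresholds = lab_rule_thresholds()) {
  simultaneity <- match.arg(simultaneity)
  labs <- check_units(labs)
  hormone <- labs$date[(labs$item == "FT4" & labs$value >= thresholds$ft4_ge) |
                         (labs$item == "FT3" & labs$value >= thresholds$ft3_ge)]
  tsh <- labs$date[labs$item == "TSH" & labs$value <= thresholds$tsh_le]
  if (simultaneity == "same_date") {
    dates <- intersect(as.character(hormone), as.character(tsh))
    hit <- length(dates) >= 1L
    ev <- as.Date(dates)
  } else {
    hit <- length(hormone) >= 1L && length(tsh) >= 1L
    ev <- unique(c(hormone, tsh))
  }
  adjudication_row(one_patient_id(labs), "hyperthyroidism",
                   if (hit) "true_case" else "other_case",
                   if (hit) ev else as.Date(character()))
}

one_patient_id <- function(labs) {
  if (nrow(labs) && "patient_id" %in% names(labs)) labs$patient_id[1]
  else NA_character_
}

#' Detect an acute serum-creatinine elevation around an index month
#'
#' Scans creatinine observations dated within one calendar month before or
#' after the index month for an acute rise: the value must exceed its
#' baseline by at least 0.3 mg/dL, or reach at least 150% of it. The
#' baseline is the patient's previous creatinine from the past three
#' calendar months — by default the most recent observation strictly before
#' the candidate value (`baseline_stat = "latest"`; `"min"` and `"mean"`
#' summarise all baseline candidates instead). An observation with no
#' baseline in reach cannot qualify; if no observation qualifies the
#' function returns `NULL`. A zero baseline disables the ratio branch only.
#'
#' @param cre_series One patient's creatinine observations (tibble with
#'   `date`, `value`; mg/dL), any row order.
#' @param index_month `"YYYY-MM"` month anchoring the evaluation window.
#' @param baseline_stat `"latest"`, `"min"` or `"mean"`.
#' @param thresholds See [lab_rule_thresholds()].
#' @return A list of class `cre_elevation_finding` (`baseline_value`,
#'   `baseline_date`, `elevated_value`, `elevated_date`, `absolute_delta`,
#'   `ratio`) for the earliest qualifying observation, or `NULL`.
#' @export
detect_acute_cre_elevation <- function(cre_series, index_month,
                                       baseline_stat = c("latest", "min",
                                                         "mean"),
                                       thresholds = lab_rule_thresholds()) {
  baseline_stat <- match.arg(baseline_stat)
  if (is.null(cre_series) || !nrow(cre_series)) return(NULL)
  ord <- order(cre_series$date)
  dates <- as.Date(cre_series$date)[ord]
  values <- cre_series$value[ord]
  mi <- month_index(date_month(dates))
  idx_mi <- month_index(index_month)

  in_window <- which(mi >= idx_mi - 1L & mi <= idx_mi + 1L)
  for (i in in_window) {
    cand <- which(dates < dates[i] & mi >= mi[i] - 3L)
    if (!length(cand)) next
    base <- switch(baseline_stat,
      latest = {
        j <- cand[which.max(as.numeric(dates[cand]))]
        list(value = values[j], date = dates[j])
      },
      min = {
        j <- cand[which.min(values[cand])]
        list(value = values[j], date = dates[j])
      },
      mean = list(value = mean(values[cand]), date = max(dates[cand]))
    )
    delta <- values[i] - base$value
    ratio <- if (base$value > 0) values[i] / base$value else NA_real_
    if (delta >= thresholds$cre_delta_ge ||
        (!is.na(ratio) && ratio >= thresholds$cre_ratio_ge)) {
      return(structure(
        list(baseline_value = base$value, baseline_date = base$date,
             elevated_value = values[i], elevated_date = dates[i],
             absolute_delta = delta, ratio = ratio),
        class = "cre_elevation_finding"))
    }
  }
  NULL
}

#' @export
print.cre_elevation_finding <- function(x, ...) {
  cat(sprintf(
    "<cre_elevation_finding> %.2f (%s) -> %.2f (%s); delta %.2f, ratio %s\n",
    x$baseline_value, x$baseline_date, x$elevated_value, x$elevated_date,
    x$absolute_delta,
    if (is.na(x$ratio)) "NA" else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Prior-creatinine stratum
#'
#' Classifies the baseline creatinine used by the acute-elevation rule into
#' the screening strata `<=1.2`, `(1.2,2.0]`, `>2.0` mg/dL. The strata exist
#' to set aside patients whose creatinine was already chronically high
#' (long-term dialysis, renal transplantation) before the index month;
#' `"no_baseline"` is returned when no prior value exists in the three-month
#' look-back.
#'
#' @inheritParams detect_acute_cre_elevation
#' @return One of `"<=1.2"`, `"(1.2,2.0]"`, `">2.0"`, `"no_baseline"`.
#' @export
stratify_prior_cre <- function(cre_series, index_month,
                               baseline_stat = c("latest", "min", "mean"),
                               thresholds = lab_rule_thresholds()) {
  baseline_stat <- match.arg(baseline_stat)
  finding <- detect_acute_cre_elevation(cre_series, index_month,
                                        baseline_stat, thresholds)
  base <- if (!is.null(finding)) {
    finding$baseline_value
  } else {
    first_baseline(cre_series, index_month, baseline_stat)
  }
  if (is.na(base)) return("no_baseline")
  if (base <= 1.2) "<=1.2" else if (base <= 2.0) "(1.2,2.0]" else ">2.0"
}

# baseline of the earliest in-window observation that has one, used when the
# elevation rule did not fire but a stratum is still wanted
first_baseline <- function(cre_series, index_month, baseline_stat) {
  if (is.null(cre_series) || !nrow(cre_series)) return(NA_real_)
  ord <- order(cre_series$date)
  dates <- as.Date(cre_series$date)[ord]
  values <- cre_series$value[ord]
  mi <- month_index(date_month(dates))
  idx_mi <- month_index(index_month)
  for (i in which(mi >= idx_mi - 1L & mi <= idx_mi + 1L)) {
    cand <- which(dates < dates[i] & mi >= mi[i] - 3L)
    if (!length(cand)) next
    return(switch(baseline_stat,
                  latest = values[cand[which.max(as.numeric(dates[cand]))]],
                  min = min(values[cand]),
                  mean = mean(values[cand])))
  }
  NA_real_
}

#' Adjudicate a set of potential cases
#'
#' Labels every potential case `true_case` or `other_case`. Method-1
#' outcomes (diabetes, dyslipidemia, hyperthyroidism) are adjudicated from
#' the patient's laboratory results by the threshold rules. For acute renal
#' failure the original study reviewed medical records; here a supplied
#' ground-truth table (e.g. from [generate_cohort()]) stands in for that
#' chart review, and each case additionally receives its prior-creatinine
#' stratum. Without a truth table, acute-renal-failure cases are labelled by
#' the creatinine rule itself (which every extracted case satisfies by
#' construction).
#'
#' @param potential_cases Tibble from [extract_potential_cases()].
#' @param cohort The [ehr_cohort()] the cases came from (supplies labs).
#' @param truth Optional ground-truth tibble (`patient_id`, `outcome`,
#'   `is_case`) standing in for medical-record review of acute renal
#'   failure.
#' @param diabetes_mode,simultaneity,baseline_stat,thresholds Rule switches
#'   passed through to the per-outcome rules.
#' @return `potential_cases` with `label`, `stratum` and evidence columns
#'   appended; every input case appears exactly once.
#' @export
adjudicate_cohort <- function(potential_cases, cohort, truth = NULL,
                              diabetes_mode = "mixed",
                              simultaneity = "same_date",
                              baseline_stat = "latest",
                              thresholds = lab_rule_thresholds()) {
  if (!nrow(potential_cases)) {
    return(dplyr::mutate(potential_cases, label = character(0),
                         stratum = character(0), n_evidence = integer(0)))
  }
  missing <- setdiff(unique(potential_cases$patient_id),
                     cohort_patient_ids(cohort))
  if (length(missing)) {
    rlang::abort(paste0("no timeline for adjudicated patient(s): ",
                        paste(utils::head(missing, 5L), collapse = ", ")),
                 class = "phenovalid_data_error")
  }
  labs <- suppressWarnings(check_units(cohort$labs))

  out <- vector("list", 0L)
  for (oc in unique(potential_cases$outcome)) {
    cases <- potential_cases[potential_cases$outcome == oc, , drop = FALSE]
    if (oc == "acute_renal_failure") {
      out[[length(out) + 1L]] <-
        adjudicate_arf_cases(cases, labs, truth, baseline_stat, thresholds)
    } else {
      qual <- switch(oc,
        diabetes = qualifying_patients_diabetes(labs, diabetes_mode,
                                                thresholds),
        dyslipidemia = qualifying_patients_dyslipidemia(labs, thresholds),
        hyperthyroidism = qualifying_patients_hyperthyroidism(labs,
                                                              simultaneity,
                                                              thresholds),
        rlang::abort(paste0("no adjudication rule for outcome: ", oc),
                     class = "phenovalid_config_error"))
      hit <- cases$patient_id %in% qual$patient_id
      nev <- qual$n_evidence[match(cases$patient_id, qual$patient_id)]
      out[[length(out) + 1L]] <- dplyr::mutate(
        cases,
        label = ifelse(hit, "true_case", "other_case"),
        n_evidence = ifelse(hit, nev, 0L),
        stratum = NA_character_)
    }
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$outcome, .data$def_id, .data$source,
                 .data$patient_id)
}

# vectorized per-patient qualification used by adjudicate_cohort(); the
# scalar adjudicate_*() functions above are the reference implementation and
# the two routes are pinned together by tests
qualifying_patients_diabetes <- function(labs, mode, thresholds) {
  glu <- labs[(labs$item == "FPG" & labs$value >= thresholds$fpg_ge) |
                (labs$item == "casual_glucose" &
                   labs$value >= thresholds$casual_glucose_ge), ,
              drop = FALSE]
  a1c <- labs[labs$item == "HbA1c" & labs$value >= thresholds$hba1c_ge, ,
              drop = FALSE]
  if (mode == "mixed") {
    q <- dplyr::distinct(dplyr::bind_rows(glu, a1c), .data$patient_id,
                         .data$date)
    q <- dplyr::count(q, .data$patient_id, name = "n_evidence")
    q[q$n_evidence >= 2L, , drop = FALSE]
  } else {
    per <- function(tbl) {
      d <- dplyr::distinct(tbl, .data$patient_id, .data$date)
      dplyr::count(d, .data$patient_id, name = "n_evidence")
    }
    q <- dplyr::bind_rows(per(glu), per(a1c))
    q <- dplyr::summarise(dplyr::group_by(q, .data$patient_id),
                          n_evidence = max(.data$n_evidence),
                          .groups = "drop")
    q[q$n_evidence >= 2L, , drop = FALSE]
  }
}

qualifying_patients_dyslipidemia <- function(labs, thresholds) {
  hit <- labs[(labs$item == "LDL" & labs$value >= thresholds$ldl_ge) |
                (labs$item == "HDL" & labs$value < thresholds$hdl_lt) |
                (labs$item == "TG" & labs$value >= thresholds$tg_ge), ,
              drop = FALSE]
  dplyr::count(dplyr::distinct(hit, .data$patient_id, .data$date),
               .data$patient_id, name = "n_evidence")
}

qualifying_patients_hyperthyroidism <- function(labs, simultaneity,
                                                thresholds) {
  hormone <- dplyr::distinct(
    labs[(labs$item == "FT4" & labs$value >= thresholds$ft4_ge) |
           (labs$item == "FT3" & labs$value >= thresholds$ft3_ge), ,
         drop = FALSE], .data$patient_id, .data$date)
  tsh <- dplyr::distinct(
    labs[labs$item == "TSH" & labs$value <= thresholds$tsh_le, ,
         drop = FALSE], .data$patient_id, .data$date)
  if (simultaneity == "same_date") {
    both <- dplyr::inner_join(hormone, tsh, by = c("patient_id", "date"))
    dplyr::count(both, .data$patient_id, name = "n_evidence")
  } else {
    both <- dplyr::inner_join(dplyr::distinct(hormone, .data$patient_id),
                              dplyr::distinct(tsh, .data$patient_id),
                              by = "patient_id")
    dplyr::mutate(both, n_evidence = 1L)
  }
}

adjudicate_arf_cases <- function(cases, labs, truth, baseline_stat,
                                 thresholds) {
  cre <- labs[labs$item == "Cre", , drop = FALSE]
  cre_by <- split(seq_len(nrow(cre)), cre$patient_id)
  truth_key <- if (!is.null(truth)) {
    stats::setNames(truth$is_case, paste(truth$patient_id, truth$outcome))
  }
  label <- character(nrow(cases))
  stratum <- character(nrow(cases))
  nev <- integer(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    series <- cre[cre_by[[cases$patient_id[i]]] %||% integer(), ,
                  drop = FALSE]
    stratum[i] <- stratify_prior_cre(series, cases$index_month[i],
                                     baseline_stat, thresholds)
    nev[i] <- nrow(series)
    label[i] <- if (!is.null(truth_key)) {
      truthy <- truth_key[paste(cases$patient_id[i], cases$outcome[i])]
      if (isTRUE(unname(truthy))) "true_case" else "other_case"
    } else {
      finding <- detect_acute_cre_elevation(series, cases$index_month[i],
                                            baseline_stat, thresholds)
      if (!is.null(finding)) "true_case" else "other_case"
    }
  }
  dplyr::mutate(cases, label = label, n_evidence = nev, stratum = stratum)
}
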