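#' Outcome definition registry
#'
#' The eight Method-1 extraction conditions combine coded disease names,
#' drug prescriptions and medical-practice items with a month-level temporal
#' constraint; the single Method-2 condition combines a disease name with an
#' acute serum-creatinine elevation. Each row records which event kinds the
#' definition uses, the optional diagnosis-to-prescription interval limit
#' (months), the index-month rule, and which data sources can supply it:
#' practice codes exist only in claims data, laboratory results only in the
#' EMR export store, so `D4`–`D6_2` are claims-only and `M2_D1` is
#' ssmix-only.
#'
#' @return A tibble with one row per definition.
#' @examples
#' outcome_definitions()
#' @export
outcome_definitions <- function() {
  tibble::tribble(
    ~def_id, ~label, ~uses_disease, ~uses_drug, ~uses_practice, ~uses_lab,
    ~interval_limit_months, ~index_rule, ~sources,
    "D1", "Disease name only", TRUE, FALSE, FALSE, FALSE,
    NA_integer_, "dx_month", c("ssmix", "claims"),
    "D2", "Drug only", FALSE, TRUE, FALSE, FALSE,
    NA_integer_, "rx_month", c("ssmix", "claims"),
    "D3_1", "Disease name and drug (no interval limit)", TRUE, TRUE, FALSE,
    FALSE, NA_integer_, "rx_month", c("ssmix", "claims"),
    "D3_2", "Disease name and drug (interval <= 1 month)", TRUE, TRUE, FALSE,
    FALSE, 1L, "rx_month", c("ssmix", "claims"),
    "D4", "Disease name and medical practice", TRUE, FALSE, TRUE, FALSE,
    NA_integer_, "dx_month", "claims",
    "D5", "Drug and medical practice", FALSE, TRUE, TRUE, FALSE,
    NA_integer_, "rx_month", "claims",
    "D6_1", "Disease name, practice and drug (no interval limit)", TRUE, TRUE,
    TRUE, FALSE, NA_integer_, "rx_month", "claims",
    "D6_2", "Disease name, practice and drug (interval <= 1 month)", TRUE,
    TRUE, TRUE, FALSE, 1L, "rx_month", "claims",
    "M2_D1", "Disease name and acute serum-Cre elevation", TRUE, FALSE, FALSE,
    TRUE, NA_integer_, "dx_month", "ssmix"
  )
}

method1_def_ids <- function() {
  c("D1", "D2", "D3_1", "D3_2", "D4", "D5", "D6_1", "D6_2")
}

definition_sources <- function(def_id) {
  defs <- outcome_definitions()
  defs$sources[[match(def_id, defs$def_id)]]
}

#' Extraction options
#'
#' Switches that resolve points the study protocol leaves open.
#'
#' @param definitive_only Should only non-suspected ("definitive") diagnoses
#'   anchor a definition? Default `TRUE`: claims carry a suspected-diagnosis
#'   flag and the definitions speak of the initial *definitive* diagnosis.
#' @param d5_literal Definition 5 ("drug and medical practice") as published
#'   carries a temporal sentence that appears copied from Definition 4
#'   (diagnosis month equals practice month). Default `FALSE` implements the
#'   predicate its data sources imply — the month of medical practice equals
#'   the month of initial drug prescription; `TRUE` applies the literal
#'   sentence (requiring a diagnosis month equal to a practice month, indexed
#'   at the prescription month).
#' @param washout_months Months of event-free run-in required before an index
#'   month counts as new onset. Default `0`: new onset means first occurrence
#'   within the observation window.
#' @return A named list of class `extract_options`.
#' @export
extract_options <- function(definitive_only = TRUE, d5_literal = FALSE,
                            washout_months = 0L) {
  structure(list(definitive_only = definitive_only,
                 d5_literal = d5_literal,
                 washout_months = as.integer(washout_months)),
            class = "extract_options")
}

# matching helpers -----------------------------------------------------------

match_diagnoses <- function(dx, codes, definitive_only = TRUE) {
  hit <- dx$icd10 %in% codes$disease_codes$icd10 |
    dx$claim_code %in% codes$disease_codes$claim_code
  if (definitive_only) hit <- hit & !dx$suspected
  dx[hit, , drop = FALSE]
}

match_prescriptions <- function(rx, codes) {
  rx[substr(rx$yj_code, 1L, 7L) %in% codes$drug_codes, , drop = FALSE]
}

match_practices <- function(px, codes) {
  px[px$practice_code %in% codes$practice_codes, , drop = FALSE]
}

#' First matching event month
#'
#' The month in which an event matching the code set initially occurs during
#' the observation window — the anchor of every "initial diagnosis" /
#' "initial prescription" clause.
#'
#' @param timeline A single-patient [ehr_cohort()] (see [patient_timeline()]).
#' @param codes A [code_list()].
#' @param kind `"diagnosis"`, `"prescription"` or `"practice"`.
#' @param source Restrict to `"claims"` or `"ssmix"` events; `NULL` uses both.
#' @param definitive_only For diagnoses, require the suspected flag to be
#'   unset.
#' @return The earliest matching `"YYYY-MM"` month, or `NA_character_`.
#' @export
first_event_month <- function(timeline, codes,
                              kind = c("diagnosis", "prescription", "practice"),
                              source = NULL, definitive_only = TRUE) {
  kind <- match.arg(kind)
  tbl <- switch(kind,
    diagnosis = match_diagnoses(timeline$diagnoses, codes, definitive_only),
    prescription = match_prescriptions(timeline$prescriptions, codes),
    practice = match_practices(timeline$practices, codes)
  )
  if (!is.null(source)) tbl <- tbl[tbl$source %in% source, , drop = FALSE]
  if (!nrow(tbl)) return(NA_character_)
  tbl$month[which.min(month_index(tbl$month))]
}

# the shared month-index predicate behind evaluate_method1() and the
# vectorized extractor. dx_mi / rx_mi are scalars (NA = absent); px_mi an
# integer vector of matching practice months.
method1_predicate <- function(def_id, dx_mi, rx_mi, px_mi,
                              d5_literal = FALSE) {
  has_dx <- !is.na(dx_mi)
  has_rx <- !is.na(rx_mi)
  hit <- switch(def_id,
    D1 = has_dx,
    D2 = has_rx,
    D3_1 = has_dx && has_rx && dx_mi <= rx_mi,
    D3_2 = has_dx && has_rx && dx_mi <= rx_mi && (rx_mi - dx_mi) <= 1L,
    D4 = has_dx && any(px_mi == dx_mi),
    D5 = if (d5_literal) {
      has_rx && has_dx && any(px_mi == dx_mi)
    } else {
      has_rx && any(px_mi == rx_mi)
    },
    D6_1 = has_dx && has_rx &&
      any(px_mi >= dx_mi & px_mi <= rx_mi),
    D6_2 = has_dx && has_rx &&
      any(px_mi >= dx_mi & px_mi <= rx_mi) && (rx_mi - dx_mi) <= 1L,
    rlang::abort(paste0("unknown Method-1 definition: ", def_id),
                 class = "phenovalid_config_error")
  )
  isTRUE(hit)
}

#' Evaluate one Method-1 definition on one patient timeline
#'
#' Applies the definition's component-existence and temporal requirements at
#' month granularity and, when they hold, returns the potential case with its
#' index month (the initial diagnosis month for `D1`/`D4`, otherwise the
#' initial prescription month). Months are unordered within themselves: a
#' diagnosis and a prescription in the same calendar month satisfy "same as
#' or prior to" regardless of day order, which month-level claims data cannot
#' resolve.
#'
#' @param timeline A single-patient [ehr_cohort()].
#' @param def_id One of `outcome_definitions()`'s Method-1 ids.
#' @param codes A [code_list()].
#' @param source `"claims"` or `"ssmix"`; must be a source the definition
#'   supports (practice-based definitions are claims-only).
#' @param options An [extract_options()].
#' @return A one-row tibble (`patient_id`, `outcome`, `def_id`, `source`,
#'   `index_month`, `dx_month`, `rx_month`) or `NULL` when the definition
#'   does not fire.
#' @export
evaluate_method1 <- function(timeline, def_id, codes, source = "claims",
                             options = extract_options()) {
  if (!source %in% definition_sources(def_id)) {
    rlang::abort(sprintf(
      "definition %s is not available from source '%s'", def_id, source),
      class = "phenovalid_config_error")
  }
  dx_month <- first_event_month(timeline, codes, "diagnosis", source,
                                options$definitive_only)
  rx_month <- first_event_month(timeline, codes, "prescription", source)
  px <- match_practices(timeline$practices, codes)
  px <- px[px$source %in% source, , drop = FALSE]
  px_mi <- if (nrow(px)) month_index(px$month) else integer()
  dx_mi <- if (is.na(dx_month)) NA_integer_ else month_index(dx_month)
  rx_mi <- if (is.na(rx_month)) NA_integer_ else month_index(rx_month)

  if (!method1_predicate(def_id, dx_mi, rx_mi, px_mi, options$d5_literal)) {
    return(NULL)
  }
  index_rule <- outcome_definitions()$index_rule[
    match(def_id, outcome_definitions()$def_id)]
  index_month <- if (index_rule == "dx_month") dx_month else rx_month
  if (options$washout_months > 0L &&
      month_index(index_month) <
        timeline$window$start_mi + options$washout_months) {
    return(NULL)
  }
  tibble::tibble(
    patient_id = cohort_patient_ids(timeline)[1],
    outcome = codes$outcome, def_id = def_id, source = source,
    index_month = index_month, dx_month = dx_month, rx_month = rx_month
  )
}

#' Evaluate the Method-2 definition on one patient timeline
#'
#' Fires when the patient has an initial definitive acute-renal-failure
#' diagnosis (month `m`) in the EMR export and some serum-creatinine
#' observation dated within calendar months `m - 1` to `m + 1` shows an
#' acute elevation — an increase of at least 0.3 mg/dL, or to at least 150%,
#' over the most recent creatinine of the preceding three months (see
#' [detect_acute_cre_elevation()]). The index month is the diagnosis month.
#'
#' @inheritParams evaluate_method1
#' @param baseline_stat Baseline statistic passed through to the Cre rule.
#' @return A one-row tibble with the triggering creatinine pair as evidence,
#'   or `NULL`.
#' @export
evaluate_method2 <- function(timeline, codes, options = extract_options(),
                             baseline_stat = c("latest", "min", "mean")) {
  baseline_stat <- match.arg(baseline_stat)
  dx_month <- first_event_month(timeline, codes, "diagnosis", "ssmix",
                                options$definitive_only)
  if (is.na(dx_month)) return(NULL)
  cre <- timeline$labs[timeline$labs$item == "Cre", , drop = FALSE]
  finding <- detect_acute_cre_elevation(cre, dx_month,
                                        baseline_stat = baseline_stat)
  if (is.null(finding)) return(NULL)
  if (options$washout_months > 0L &&
      month_index(dx_month) <
        timeline$window$start_mi + options$washout_months) {
    return(NULL)
  }
  tibble::tibble(
    patient_id = cohort_patient_ids(timeline)[1],
    outcome = codes$outcome, def_id = "M2_D1", source = "ssmix",
    index_month = dx_month, dx_month = dx_month, rx_month = NA_character_,
    cre_baseline = finding$baseline_value,
    cre_elevated = finding$elevated_value
  )
}

#' Extract potential cases from a cohort
#'
#' Applies the selected outcome definitions to every patient and returns the
#' automatically extracted group — the potential cases (count "A") that
#' adjudication will later classify as true or other cases. At most one case
#' is produced per (patient, outcome, definition, source): the definitions
#' describe new onset, anchored at initial events. The result is
#' deterministically ordered and independent of input row order.
#'
#' @param cohort A (pseudonymized) [ehr_cohort()].
#' @param code_lists Named list of [code_list()] objects (see
#'   [default_code_lists()]).
#' @param def_ids Definitions to apply; defaults to all nine.
#' @param sources Data sources to draw on; each definition runs on the
#'   intersection of this set with its own supported sources.
#' @param options An [extract_options()].
#' @return A tibble of potential cases with index months and evidence
#'   columns (`dx_month`, `rx_month`, creatinine pair for `M2_D1`).
#' @export
extract_potential_cases <- function(cohort, code_lists,
                                    def_ids = outcome_definitions()$def_id,
                                    sources = c("ssmix", "claims"),
                                    options = extract_options()) {
  defs <- outcome_definitions()
  bad <- setdiff(def_ids, defs$def_id)
  if (length(bad)) {
    rlang::abort(paste0("unknown definition id(s): ",
                        paste(bad, collapse = ", ")),
                 class = "phenovalid_config_error")
  }
  out <- list()
  for (codes in code_lists) {
    # acute renal failure is validated through the creatinine definition
    # only; the laboratory-adjudicated outcomes use the Method-1 definitions
    if (codes$outcome == "acute_renal_failure") {
      if ("M2_D1" %in% def_ids && "ssmix" %in% sources) {
        out[[length(out) + 1L]] <-
          extract_method2_vectorized(cohort, codes, options)
      }
      next
    }
    for (src in sources) {
      m1 <- intersect(def_ids, method1_def_ids())
      m1 <- m1[vapply(m1, function(d) src %in% definition_sources(d), TRUE)]
      if (length(m1)) {
        out[[length(out) + 1L]] <-
          extract_method1_vectorized(cohort, codes, m1, src, options)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    return(tibble::tibble(
      patient_id = character(), outcome = character(), def_id = character(),
      source = character(), index_month = character(),
      dx_month = character(), rx_month = character(),
      cre_baseline = numeric(), cre_elevated = numeric()))
  }
  dplyr::arrange(res, .data$outcome, .data$def_id, .data$source,
                 .data$patient_id)
}

# vectorized Method-1 extraction: per-patient first-event summaries via
# grouped minima, then the shared predicate row by row (cheap scalars)
extract_method1_vectorized <- function(cohort, codes, def_ids, src, options) {
  dx <- match_diagnoses(cohort$diagnoses, codes, options$definitive_only)
  dx <- dx[dx$source == src, , drop = FALSE]
  rx <- match_prescriptions(cohort$prescriptions, codes)
  rx <- rx[rx$source == src, , drop = FALSE]
  px <- match_practices(cohort$practices, codes)
  px <- px[px$source == src, , drop = FALSE]

  first_mi <- function(tbl) {
    if (!nrow(tbl)) {
      return(tibble::tibble(patient_id = character(), mi = integer()))
    }
    tbl$mi <- month_index(tbl$month)
    dplyr::summarise(dplyr::group_by(tbl, .data$patient_id),
                     mi = min(.data$mi), .groups = "drop")
  }
  dxf <- dplyr::rename(first_mi(dx), dx_mi = "mi")
  rxf <- dplyr::rename(first_mi(rx), rx_mi = "mi")
  pats <- dplyr::full_join(dxf, rxf, by = "patient_id")
  if (!nrow(pats)) return(NULL)

  # per-patient practice-month summaries relative to the first dx / rx
  if (nrow(px)) {
    px$mi <- month_index(px$month)
    pxj <- dplyr::inner_join(px[c("patient_id", "mi")], pats,
                             by = "patient_id")
    pxs <- dplyr::summarise(
      dplyr::group_by(pxj, .data$patient_id),
      px_eq_dx = any(!is.na(.data$dx_mi) & .data$mi == .data$dx_mi),
      px_eq_rx = any(!is.na(.data$rx_mi) & .data$mi == .data$rx_mi),
      px_between = any(!is.na(.data$dx_mi) & !is.na(.data$rx_mi) &
                         .data$mi >= .data$dx_mi & .data$mi <= .data$rx_mi),
      .groups = "drop")
    pats <- dplyr::left_join(pats, pxs, by = "patient_id")
  } else {
    pats$px_eq_dx <- FALSE; pats$px_eq_rx <- FALSE; pats$px_between <- FALSE
  }
  pats$px_eq_dx <- dplyr::coalesce(pats$px_eq_dx, FALSE)
  pats$px_eq_rx <- dplyr::coalesce(pats$px_eq_rx, FALSE)
  pats$px_between <- dplyr::coalesce(pats$px_between, FALSE)

  has_dx <- !is.na(pats$dx_mi)
  has_rx <- !is.na(pats$rx_mi)
  seq_le <- has_dx & has_rx & pats$dx_mi <= pats$rx_mi
  within1 <- has_dx & has_rx & (pats$rx_mi - pats$dx_mi) <= 1L

  res <- list()
  defs <- outcome_definitions()
  for (d in def_ids) {
    hit <- switch(d,
      D1 = has_dx,
      D2 = has_rx,
      D3_1 = seq_le,
      D3_2 = seq_le & within1,
      D4 = has_dx & pats$px_eq_dx,
      D5 = if (options$d5_literal) has_rx & has_dx & pats$px_eq_dx
           else has_rx & pats$px_eq_rx,
      D6_1 = pats$px_between,
      D6_2 = pats$px_between & within1)
    idx_rule <- defs$index_rule[match(d, defs$def_id)]
    index_mi <- if (idx_rule == "dx_month") pats$dx_mi else pats$rx_mi
    if (options$washout_months > 0L) {
      hit <- hit & index_mi >= cohort$window$start_mi + options$washout_months
    }
    if (!any(hit)) next
    res[[length(res) + 1L]] <- tibble::tibble(
      patient_id = pats$patient_id[hit], outcome = codes$outcome,
      def_id = d, source = src, index_month = month_label(index_mi[hit]),
      dx_month = ifelse(is.na(pats$dx_mi[hit]), NA_character_,
                        month_label(pats$dx_mi[hit])),
      rx_month = ifelse(is.na(pats$rx_mi[hit]), NA_character_,
                        month_label(pats$rx_mi[hit])))
  }
  dplyr::bind_rows(res)
}

extract_method2_vectorized <- function(cohort, codes, options) {
  dx <- match_diagnoses(cohort$diagnoses, codes, options$definitive_only)
  dx <- dx[dx$source == "ssmix", , drop = FALSE]
  if (!nrow(dx)) return(NULL)
  dx$mi <- month_index(dx$month)
  firsts <- dplyr::summarise(dplyr::group_by(dx, .data$patient_id),
                             mi = min(.data$mi), .groups = "drop")
  cre <- cohort$labs[cohort$labs$item == "Cre", , drop = FALSE]
  cre_by <- split(seq_len(nrow(cre)), cre$patient_id)
  res <- list()
  for (i in seq_len(nrow(firsts))) {
    pid <- firsts$patient_id[i]
    series <- cre[cre_by[[pid]] %||% integer(), , drop = FALSE]
    finding <- detect_acute_cre_elevation(series, month_label(firsts$mi[i]))
    if (is.null(finding)) next
    if (options$washout_months > 0L &&
        firsts$mi[i] < cohort$window$start_mi + options$washout_months) next
    res[[length(res) + 1L]] <- tibble::tibble(
      patient_id = pid, outcome = codes$outcome, def_id = "M2_D1",
      source = "ssmix", index_month = month_label(firsts$mi[i]),
      dx_month = month_label(firsts$mi[i]), rx_month = NA_character_,
      cre_baseline = finding$baseline_value,
      cre_elevated = finding$elevated_value
    )
  }
  dplyr::bind_rows(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
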