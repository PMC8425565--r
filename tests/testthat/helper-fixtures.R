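# shared fixtures: a minimal code list, timeline builders, and independent
# brute-force oracles for the temporal predicates and the creatinine rule

test_codes <- function(outcome = "diabetes") {
  code_list(
    outcome = outcome,
    disease_codes = tibble::tibble(icd10 = "E10", claim_code = "2500014"),
    drug_codes = "3961007",
    practice_codes = "160022410"
  )
}

# events: tibble(kind in dx/rx/px, month "YYYY-MM", suspected lgl)
mk_timeline <- function(events, source = "claims",
                        window = study_window("2008-01-01", "2011-12-31"),
                        patient_id = "P1") {
  events <- tibble::as_tibble(events)
  if (!"suspected" %in% names(events)) events$suspected <- FALSE
  dx <- events[events$kind == "dx", , drop = FALSE]
  rx <- events[events$kind == "rx", , drop = FALSE]
  px <- events[events$kind == "px", , drop = FALSE]
  ehr_cohort(
    diagnoses = tibble::tibble(
      patient_id = patient_id, month = dx$month, icd10 = "E10",
      claim_code = "2500014", suspected = dx$suspected, source = source),
    prescriptions = tibble::tibble(
      patient_id = patient_id, month = rx$month, yj_code = "396100701001",
      source = source),
    practices = tibble::tibble(
      patient_id = patient_id, month = px$month,
      practice_code = "160022410", source = "claims"),
    window = window
  )
}

mk_labs <- function(item, value, date, patient_id = "P1") {
  tibble::tibble(
    patient_id = patient_id, date = as.Date(date), item = item,
    value = value, unit = unname(phenovalid:::lab_unit_table()[item]))
}

# independent oracle for the Method-1 temporal predicates, written as plain
# nested conditionals over the raw event list (month indices)
oracle_method1 <- function(def_id, events, d5_literal = FALSE) {
  mi <- month_index(events$month)
  dx <- mi[events$kind == "dx" & !events$suspected]
  rx <- mi[events$kind == "rx"]
  px <- mi[events$kind == "px"]
  d <- if (length(dx)) min(dx) else NA_integer_
  r <- if (length(rx)) min(rx) else NA_integer_

  if (def_id == "D1") {
    if (!is.na(d)) return(list(hit = TRUE, index = d))
  } else if (def_id == "D2") {
    if (!is.na(r)) return(list(hit = TRUE, index = r))
  } else if (def_id == "D3_1") {
    if (!is.na(d) && !is.na(r)) {
      if (d <= r) return(list(hit = TRUE, index = r))
    }
  } else if (def_id == "D3_2") {
    if (!is.na(d) && !is.na(r)) {
      if (d <= r && r - d <= 1) return(list(hit = TRUE, index = r))
    }
  } else if (def_id == "D4") {
    if (!is.na(d)) {
      for (p in px) if (p == d) return(list(hit = TRUE, index = d))
    }
  } else if (def_id == "D5") {
    if (d5_literal) {
      if (!is.na(r) && !is.na(d)) {
        for (p in px) if (p == d) return(list(hit = TRUE, index = r))
      }
    } else {
      if (!is.na(r)) {
        for (p in px) if (p == r) return(list(hit = TRUE, index = r))
      }
    }
  } else if (def_id == "D6_1") {
    if (!is.na(d) && !is.na(r)) {
      for (p in px) {
        if (d <= p && p <= r) return(list(hit = TRUE, index = r))
      }
    }
  } else if (def_id == "D6_2") {
    if (!is.na(d) && !is.na(r) && r - d <= 1) {
      for (p in px) {
        if (d <= p && p <= r) return(list(hit = TRUE, index = r))
      }
    }
  } else {
    stop("unknown definition in oracle: ", def_id)
  }
  list(hit = FALSE, index = NA_integer_)
}

# enumerate all event multisets of size <= max_events over a month grid;
# kinds: definitive dx, suspected dx, rx, px
enumerate_timelines <- function(months, max_events = 4L) {
  atoms <- tidyr::expand_grid(
    kind = c("dx", "sdx", "rx", "px"), month = months)
  atoms$id <- seq_len(nrow(atoms))
  out <- list(tibble::tibble(kind = character(), month = character(),
                             suspected = logical()))
  # multisets as non-decreasing index tuples with repetition
  grid_ids <- seq_len(nrow(atoms))
  rec <- function(prefix, start, k) {
    if (k == 0L) {
      ev <- atoms[prefix, , drop = FALSE]
      out[[length(out) + 1L]] <<- tibble::tibble(
        kind = ifelse(ev$kind == "sdx", "dx", ev$kind),
        month = ev$month, suspected = ev$kind == "sdx")
      return(invisible())
    }
    for (i in start:length(grid_ids)) rec(c(prefix, i), i, k - 1L)
  }
  for (k in seq_len(max_events)) rec(integer(), 1L, k)
  out
}

# independent oracle for the acute creatinine-elevation rule: exhaustive
# pairwise scan over all (baseline, observation) pairs
oracle_cre <- function(dates, values, index_month,
                       delta = 0.3, ratio = 1.5) {
  idx <- month_index(index_month)
  hits <- list()
  for (i in seq_along(dates)) {
    mi_i <- month_index(date_month(dates[i]))
    if (mi_i < idx - 1L || mi_i > idx + 1L) next
    bj <- NA_integer_
    for (j in seq_along(dates)) {
      if (j == i) next
      if (dates[j] < dates[i] &&
          month_index(date_month(dates[j])) >= mi_i - 3L) {
        if (is.na(bj) || dates[j] > dates[bj]) bj <- j
      }
    }
    if (is.na(bj)) next
    fires <- (values[i] - values[bj] >= delta) ||
      (values[bj] > 0 && values[i] / values[bj] >= ratio)
    if (fires) hits[[length(hits) + 1L]] <- list(i = i, baseline = bj)
  }
  if (!length(hits)) return(NULL)
  first <- which.min(vapply(hits, function(h) as.numeric(dates[h$i]), 0))
  hits[[first]]
}

# random creatinine series with distinct dates (date ties would make the
# "most recent baseline" ambiguous between equally-dated observations)
random_cre_series <- function(n_obs, index_month = "2009-06") {
  idx_start <- as.Date(paste0(index_month, "-01"))
  days <- sample(seq(idx_start - 150, idx_start + 59, by = "day"), n_obs)
  tibble::tibble(
    patient_id = "P1", date = sort(days), item = "Cre",
    value = round(stats::runif(n_obs, 0.3, 3.0), 2), unit = "mg/dL")
}
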