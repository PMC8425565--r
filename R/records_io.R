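#' Longitudinal coded-event cohort container
#'
#' An `ehr_cohort` bundles the four event streams the validation pipeline
#' consumes, each as a tibble keyed by `patient_id`:
#'
#' * `diagnoses`: `patient_id, month, icd10, claim_code, suspected, source`
#' * `prescriptions`: `patient_id, month, yj_code, source`
#' * `practices`: `patient_id, month, practice_code, source`
#' * `labs`: `patient_id, date, item, value, unit`
#'
#' Diagnoses, prescriptions and medical-practice items are coded events at
#' calendar-month granularity (`month` is `"YYYY-MM"`); laboratory
#' observations carry full dates. `source` distinguishes the monthly claims
#' extract (`"claims"`) from the EMR export store (`"ssmix"`); practice codes
#' exist only in claims data, and laboratory results only in the EMR export.
#'
#' @param diagnoses,prescriptions,practices,labs Tibbles as described above;
#'   missing ones default to empty.
#' @param window A [study_window()]; events outside it are invalid.
#' @return An object of class `ehr_cohort`.
#' @export
ehr_cohort <- function(diagnoses = NULL, prescriptions = NULL,
                       practices = NULL, labs = NULL,
                       window = study_window()) {
  empty <- empty_cohort_tables()
  x <- structure(
    list(
      diagnoses = fill_tbl(diagnoses, empty$diagnoses),
      prescriptions = fill_tbl(prescriptions, empty$prescriptions),
      practices = fill_tbl(practices, empty$practices),
      labs = fill_tbl(labs, empty$labs),
      window = window
    ),
    class = "ehr_cohort"
  )
  validate_cohort(x)
  sort_cohort(x)
}

empty_cohort_tables <- function() {
  list(
    diagnoses = tibble::tibble(
      patient_id = character(), month = character(), icd10 = character(),
      claim_code = character(), suspected = logical(), source = character()
    ),
    prescriptions = tibble::tibble(
      patient_id = character(), month = character(), yj_code = character(),
      source = character()
    ),
    practices = tibble::tibble(
      patient_id = character(), month = character(),
      practice_code = character(), source = character()
    ),
    labs = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      item = character(), value = numeric(), unit = character()
    )
  )
}

fill_tbl <- function(x, template) {
  if (is.null(x)) return(template)
  x <- tibble::as_tibble(x)
  missing <- setdiff(names(template), names(x))
  if (length(missing)) {
    rlang::abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
                 class = "phenovalid_data_error")
  }
  x[names(template)]
}

validate_cohort <- function(x) {
  for (tbl in c("diagnoses", "prescriptions", "practices")) {
    m <- x[[tbl]]$month
    if (length(m)) {
      mi <- month_index(m)
      bad <- mi < x$window$start_mi | mi > x$window$end_mi
      if (any(bad)) {
        rlang::abort(sprintf("%d %s event(s) outside the study window",
                             sum(bad), tbl),
                     class = "phenovalid_data_error")
      }
    }
  }
  if (nrow(x$labs)) {
    if (any(x$labs$value < 0, na.rm = TRUE)) {
      rlang::abort("negative laboratory values", class = "phenovalid_data_error")
    }
  }
  bad_icd <- x$diagnoses$icd10[!grepl("^[A-Z][0-9]{2}", x$diagnoses$icd10)]
  if (length(bad_icd)) {
    rlang::abort(paste0("malformed ICD-10 code(s): ",
                        paste(unique(utf8_head(bad_icd)), collapse = ", ")),
                 class = "phenovalid_data_error")
  }
  invisible(x)
}

utf8_head <- function(x, n = 5L) utils::head(x, n)

sort_cohort <- function(x) {
  x$diagnoses <- dplyr::arrange(x$diagnoses, .data$patient_id, .data$month,
                                .data$claim_code)
  x$prescriptions <- dplyr::arrange(x$prescriptions, .data$patient_id,
                                    .data$month, .data$yj_code)
  x$practices <- dplyr::arrange(x$practices, .data$patient_id, .data$month,
                                .data$practice_code)
  x$labs <- dplyr::arrange(x$labs, .data$patient_id, .data$date, .data$item)
  x
}

#' @export
print.ehr_cohort <- function(x, ...) {
  ids <- cohort_patient_ids(x)
  cat(sprintf(
    "<ehr_cohort> %d patients | %d dx, %d rx, %d practice, %d lab records\n",
    length(ids), nrow(x$diagnoses), nrow(x$prescriptions),
    nrow(x$practices), nrow(x$labs)))
  print(x$window)
  invisible(x)
}

#' @rdname ehr_cohort
#' @param x An `ehr_cohort`.
#' @export
cohort_patient_ids <- function(x) {
  sort(unique(c(x$diagnoses$patient_id, x$prescriptions$patient_id,
                x$practices$patient_id, x$labs$patient_id)))
}

#' Extract one patient's timeline
#'
#' Returns the same four-table structure restricted to a single patient —
#' the unit on which the per-patient outcome and adjudication rules operate.
#'
#' @param cohort An [ehr_cohort()].
#' @param patient_id A single patient identifier.
#' @return An `ehr_cohort` containing only that patient's events.
#' @export
patient_timeline <- function(cohort, patient_id) {
  pid <- patient_id
  out <- cohort
  out$diagnoses <- dplyr::filter(cohort$diagnoses, .data$patient_id == pid)
  out$prescriptions <- dplyr::filter(cohort$prescriptions,
                                     .data$patient_id == pid)
  out$practices <- dplyr::filter(cohort$practices, .data$patient_id == pid)
  out$labs <- dplyr::filter(cohort$labs, .data$patient_id == pid)
  out
}

# canonical unit per laboratory analyte; observations with other units are
# skipped (with a warning) by the adjudication rules
lab_unit_table <- function() {
  c(FPG = "mg/dL", casual_glucose = "mg/dL", HbA1c = "%",
    LDL = "mg/dL", HDL = "mg/dL", TG = "mg/dL",
    FT3 = "pg/mL", FT4 = "ng/dL", TSH = "uU/mL", Cre = "mg/dL")
}

## ---- claims CSV dialect ----------------------------------------------------

#' Read a monthly claims extract
#'
#' The claims dialect is a UTF-8 CSV with header
#' `patient_id,record_type,month,code,icd10,suspected`, one row per coded
#' event at calendar-month granularity. `record_type` is `DX` (diagnosis,
#' `code` = 7-digit computerized-claim disease code, `icd10` filled,
#' `suspected` 0/1), `RX` (prescription, `code` = YJ drug code) or `PX`
#' (medical-practice item, `code` = practice code).
#'
#' Malformed rows (unknown record type, malformed month, short YJ code,
#' non-7-digit claim disease code) are dropped with a warning naming the line;
#' events dated outside `window` are dropped with a message reporting the
#' count. A missing file is a fatal error.
#'
#' @param path Path to the CSV file.
#' @param window A [study_window()].
#' @return An [ehr_cohort()] with `source = "claims"` on every coded event.
#' @export
read_claims_table <- function(path, window = study_window()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("claims file not found: ", path),
                 class = "phenovalid_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      record_type = readr::col_character(),
      month = readr::col_character(),
      code = readr::col_character(),
      icd10 = readr::col_character(),
      suspected = readr::col_character()
    ),
    progress = FALSE
  )
  raw$line <- seq_len(nrow(raw)) + 1L  # header is line 1

  bad <- rep(FALSE, nrow(raw))
  note <- function(idx, why) {
    if (any(idx)) {
      warning(sprintf("dropping %d malformed claims row(s) (%s) at line(s) %s",
                      sum(idx), why,
                      paste(utils::head(raw$line[idx], 5L), collapse = ", ")),
              call. = FALSE)
    }
    idx
  }
  bad <- bad | note(!raw$record_type %in% c("DX", "RX", "PX"),
                    "unknown record_type")
  ok_month <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", raw$month)
  bad <- bad | note(!ok_month & !bad, "malformed month")
  bad <- bad | note(raw$record_type == "DX" & !grepl("^\\d{7}$", raw$code) &
                      !bad, "claim disease code is not 7 digits")
  bad <- bad | note(raw$record_type == "RX" & nchar(raw$code) < 7L & !bad,
                    "YJ code shorter than 7 characters")
  raw <- raw[!bad, , drop = FALSE]

  mi <- month_index(raw$month)
  outside <- mi < window$start_mi | mi > window$end_mi
  if (any(outside)) {
    message(sprintf("read_claims_table: dropped %d event(s) outside %s..%s",
                    sum(outside), window$start, window$end))
    raw <- raw[!outside, , drop = FALSE]
  }

  dx <- raw[raw$record_type == "DX", , drop = FALSE]
  rx <- raw[raw$record_type == "RX", , drop = FALSE]
  px <- raw[raw$record_type == "PX", , drop = FALSE]
  ehr_cohort(
    diagnoses = tibble::tibble(
      patient_id = dx$patient_id, month = dx$month, icd10 = dx$icd10,
      claim_code = dx$code,
      suspected = !is.na(dx$suspected) & dx$suspected %in% c("1", "TRUE", "true"),
      source = "claims"
    ),
    prescriptions = tibble::tibble(
      patient_id = rx$patient_id, month = rx$month, yj_code = rx$code,
      source = "claims"
    ),
    practices = tibble::tibble(
      patient_id = px$patient_id, month = px$month, practice_code = px$code,
      source = "claims"
    ),
    window = window
  )
}

#' Write a claims extract CSV
#'
#' Serialises the claims-source events of a cohort back to the claims CSV
#' dialect read by [read_claims_table()]. Laboratory observations are not
#' part of the claims dialect and are not written.
#'
#' @param cohort An [ehr_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_claims_table <- function(cohort, path) {
  dx <- dplyr::filter(cohort$diagnoses, .data$source == "claims")
  rx <- dplyr::filter(cohort$prescriptions, .data$source == "claims")
  px <- dplyr::filter(cohort$practices, .data$source == "claims")
  rows <- dplyr::bind_rows(
    tibble::tibble(patient_id = dx$patient_id, record_type = "DX",
                   month = dx$month, code = dx$claim_code, icd10 = dx$icd10,
                   suspected = as.integer(dx$suspected)),
    tibble::tibble(patient_id = rx$patient_id, record_type = "RX",
                   month = rx$month, code = rx$yj_code, icd10 = NA_character_,
                   suspected = NA_integer_),
    tibble::tibble(patient_id = px$patient_id, record_type = "PX",
                   month = px$month, code = px$practice_code,
                   icd10 = NA_character_, suspected = NA_integer_)
  )
  rows <- dplyr::arrange(rows, .data$patient_id, .data$month,
                         .data$record_type, .data$code)
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

## ---- simplified SS-MIX2-style store ----------------------------------------

# The store layout is root/<patient_id>/<YYYY-MM>/{DG1,RXE,OBX}.txt with one
# pipe-delimited record per line:
#   DG1|<date>|<icd10>|<claim_code>|<suspected 0/1>
#   RXE|<date>|<yj_code>
#   OBX|<date>|<item>|<value>|<unit>
# This is a deliberately simplified line grammar inspired by the HL7 v2.5
# segments the real export uses; it is not conformant HL7.

#' Read a simplified SS-MIX2-style export store
#'
#' Walks `root/<patient_id>/<YYYY-MM>/` folders and parses the pipe-delimited
#' `DG1` (diagnosis), `RXE` (prescription) and `OBX` (laboratory observation)
#' files. Diagnosis and prescription months are derived from each record's
#' date; records outside `window` are dropped with a message. Unparseable
#' segments and non-numeric `OBX` values are dropped with a warning naming
#' the file.
#'
#' @inheritParams read_claims_table
#' @param root Store root directory.
#' @return An [ehr_cohort()] with `source = "ssmix"` on coded events.
#' @export
read_ssmix_store <- function(root, window = study_window()) {
  if (!dir.exists(root)) {
    rlang::abort(paste0("store root not found: ", root),
                 class = "phenovalid_io_error")
  }
  files <- list.files(root, pattern = "\\.txt$", recursive = TRUE,
                      full.names = TRUE)
  dx <- list(); rx <- list(); lb <- list()
  n_outside <- 0L
  for (f in files) {
    pid <- basename(dirname(dirname(f)))
    lines <- readr::read_lines(f, progress = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) next
    parts <- strsplit(lines, "|", fixed = TRUE)
    for (p in parts) {
      seg <- p[[1]]
      d <- suppressWarnings(as.Date(p[2]))
      if (is.na(d)) {
        warning(sprintf("unparseable date in %s: %s", f,
                        paste(p, collapse = "|")), call. = FALSE)
        next
      }
      if (d < window$start || d > window$end) {
        n_outside <- n_outside + 1L
        next
      }
      if (seg == "DG1" && length(p) == 5L) {
        dx[[length(dx) + 1L]] <- tibble::tibble(
          patient_id = pid, month = date_month(d), icd10 = p[3],
          claim_code = p[4], suspected = p[5] == "1", source = "ssmix")
      } else if (seg == "RXE" && length(p) == 3L) {
        rx[[length(rx) + 1L]] <- tibble::tibble(
          patient_id = pid, month = date_month(d), yj_code = p[3],
          source = "ssmix")
      } else if (seg == "OBX" && length(p) == 5L) {
        val <- suppressWarnings(as.numeric(p[4]))
        if (is.na(val)) {
          warning(sprintf("non-numeric OBX value in %s: %s", f,
                          paste(p, collapse = "|")), call. = FALSE)
          next
        }
        lb[[length(lb) + 1L]] <- tibble::tibble(
          patient_id = pid, date = d, item = p[3], value = val, unit = p[5])
      } else {
        warning(sprintf("unparseable segment in %s: %s", f,
                        paste(p, collapse = "|")), call. = FALSE)
      }
    }
  }
  if (n_outside > 0L) {
    message(sprintf("read_ssmix_store: dropped %d record(s) outside %s..%s",
                    n_outside, window$start, window$end))
  }
  ehr_cohort(
    diagnoses = dplyr::bind_rows(dx),
    prescriptions = dplyr::bind_rows(rx),
    labs = dplyr::bind_rows(lb),
    window = window
  )
}

#' Write a simplified SS-MIX2-style store
#'
#' Serialises the ssmix-source coded events and all laboratory observations of
#' a cohort into the folder-per-patient, folder-per-month layout read by
#' [read_ssmix_store()]. Events without a recorded date (month-only claims
#' events) are written with the first day of their month.
#'
#' @param cohort An [ehr_cohort()].
#' @param root Output root directory (created if absent).
#' @param dates Optional named list with `diagnoses`/`prescriptions` `Date`
#'   vectors aligned to the cohort rows; defaults to day 1 of each month.
#' @return `root`, invisibly.
#' @export
write_ssmix_store <- function(cohort, root, dates = NULL) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dx <- dplyr::filter(cohort$diagnoses, .data$source == "ssmix")
  rx <- dplyr::filter(cohort$prescriptions, .data$source == "ssmix")
  lb <- cohort$labs

  dx_date <- if (!is.null(dates$diagnoses)) dates$diagnoses else
    as.Date(paste0(dx$month, "-01"))
  rx_date <- if (!is.null(dates$prescriptions)) dates$prescriptions else
    as.Date(paste0(rx$month, "-01"))

  recs <- dplyr::bind_rows(
    tibble::tibble(patient_id = dx$patient_id, date = dx_date,
                   line = sprintf("DG1|%s|%s|%s|%d", dx_date, dx$icd10,
                                  dx$claim_code, as.integer(dx$suspected)),
                   file = "DG1.txt"),
    tibble::tibble(patient_id = rx$patient_id, date = rx_date,
                   line = sprintf("RXE|%s|%s", rx_date, rx$yj_code),
                   file = "RXE.txt"),
    tibble::tibble(patient_id = lb$patient_id, date = lb$date,
                   line = sprintf("OBX|%s|%s|%.10g|%s", lb$date, lb$item,
                                  lb$value, lb$unit),
                   file = "OBX.txt")
  )
  if (!nrow(recs)) return(invisible(root))
  recs$month <- date_month(recs$date)
  recs <- dplyr::arrange(recs, .data$patient_id, .data$month, .data$file,
                         .data$line)
  grp <- split(recs, paste(recs$patient_id, recs$month, recs$file, sep = "/"))
  for (g in grp) {
    dir <- file.path(root, g$patient_id[1], g$month[1])
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_lines(g$line, file.path(dir, g$file[1]))
  }
  # materialise empty folders for patients with no records at all
  invisible(root)
}

## ---- code lists ------------------------------------------------------------

#' Outcome code list
#'
#' Holds the coded vocabulary one outcome definition searches: disease codes
#' as (ICD-10 small classification, 7-digit computerized-claim disease code)
#' pairs, drug codes as 7-digit YJ prefixes (the first seven digits of a YJ
#' code identify ingredient and form), and claim medical-practice codes.
#'
#' @param outcome One of `"diabetes"`, `"dyslipidemia"`, `"hyperthyroidism"`,
#'   `"acute_renal_failure"`.
#' @param disease_codes Tibble with columns `icd10`, `claim_code`.
#' @param drug_codes Character vector of 7-digit YJ prefixes (may be empty).
#' @param practice_codes Character vector of practice codes (may be empty).
#' @return An object of class `code_list`.
#' @export
code_list <- function(outcome, disease_codes, drug_codes = character(),
                      practice_codes = character()) {
  outcome <- match.arg(outcome, c("diabetes", "dyslipidemia",
                                  "hyperthyroidism", "acute_renal_failure"))
  disease_codes <- tibble::as_tibble(disease_codes)
  if (!nrow(disease_codes)) {
    rlang::abort("a code list needs at least one disease code",
                 class = "phenovalid_config_error")
  }
  if (length(drug_codes) && any(nchar(drug_codes) < 7L)) {
    rlang::abort("YJ drug prefixes must be at least 7 characters",
                 class = "phenovalid_config_error")
  }
  structure(
    list(outcome = outcome,
         disease_codes = dplyr::distinct(disease_codes[c("icd10", "claim_code")]),
         drug_codes = sort(unique(substr(drug_codes, 1L, 7L))),
         practice_codes = sort(unique(practice_codes))),
    class = "code_list"
  )
}

#' @export
print.code_list <- function(x, ...) {
  cat(sprintf("<code_list> %s: %d disease, %d drug, %d practice code(s)\n",
              x$outcome, nrow(x$disease_codes), length(x$drug_codes),
              length(x$practice_codes)))
  invisible(x)
}

#' Read code lists from CSV
#'
#' The CSV has header `outcome,kind,code,icd10` with `kind` in
#' `disease`/`drug`/`practice`; `icd10` is required for disease rows only.
#' Duplicate codes collapse to a set. A drug code shorter than 7 characters
#' is an error naming the offending row.
#'
#' @param path CSV path. The package ships a synthetic example under
#'   `system.file("extdata", "synthetic_code_lists.csv", package = "phenovalid")`.
#' @return A named list of [code_list()] objects, one per outcome present.
#' @export
read_code_list <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      outcome = readr::col_character(), kind = readr::col_character(),
      code = readr::col_character(), icd10 = readr::col_character()),
    progress = FALSE
  )
  short <- which(raw$kind == "drug" & nchar(raw$code) < 7L)
  if (length(short)) {
    rlang::abort(sprintf("drug code shorter than 7 characters at row %d: %s",
                         short[1], raw$code[short[1]]),
                 class = "phenovalid_data_error")
  }
  split(raw, raw$outcome) |>
    purrr::map(function(g) {
      dz <- g[g$kind == "disease", , drop = FALSE]
      code_list(
        outcome = g$outcome[1],
        disease_codes = tibble::tibble(icd10 = dz$icd10, claim_code = dz$code),
        drug_codes = g$code[g$kind == "drug"],
        practice_codes = g$code[g$kind == "practice"]
      )
    })
}

#' Default synthetic code lists
#'
#' The full appendix code lists of the original surveillance study are not in
#' the public record, so the package ships a synthetic stand-in covering the
#' four outcomes (the handful of codes that are public — e.g. type 1 diabetes
#' claim code 2500014 under ICD-10 E10, and the antithyroid YJ prefixes
#' 2432001/2432400/2432002 — are included verbatim; the rest are plausible
#' synthetic codes).
#'
#' @return A named list of [code_list()] objects.
#' @export
default_code_lists <- function() {
  read_code_list(system.file("extdata", "synthetic_code_lists.csv",
                             package = "phenovalid", mustWork = TRUE))
}

## ---- pseudonymization ------------------------------------------------------

#' Assign second (study) patient identifiers
#'
#' Replaces every original patient identifier with a second study ID drawn as
#' a random permutation, emulating the anonymization step performed before
#' extracted data leaves a hospital. In `"irreversible"` mode the
#' correspondence table is discarded and only the re-keyed cohort is
#' returned; in `"escrow"` mode the key table is returned as well (in the
#' original study it stayed under lock and key at each hospital so medical
#' records could be re-consulted).
#'
#' @param cohort An [ehr_cohort()].
#' @param mode `"irreversible"` or `"escrow"`.
#' @param seed Integer seed; the mapping is deterministic given the seed.
#' @return A list with `cohort` (re-keyed) and `key` (tibble
#'   `original_id`/`second_id` in escrow mode, otherwise `NULL`).
#' @export
pseudonymize <- function(cohort, mode = c("irreversible", "escrow"), seed) {
  mode <- match.arg(mode)
  ids <- cohort_patient_ids(cohort)
  if (anyDuplicated(ids)) {
    rlang::abort("duplicate original patient IDs", class = "phenovalid_data_error")
  }
  n <- length(ids)
  perm <- with_local_seed(seed, sample.int(max(n, 1L), n))
  second <- sprintf("SID%06d", perm)
  map <- stats::setNames(second, ids)

  rekey <- function(tbl) {
    if (nrow(tbl)) tbl$patient_id <- unname(map[tbl$patient_id])
    tbl
  }
  out <- cohort
  out$diagnoses <- rekey(out$diagnoses)
  out$prescriptions <- rekey(out$prescriptions)
  out$practices <- rekey(out$practices)
  out$labs <- rekey(out$labs)
  out <- sort_cohort(out)

  key <- if (mode == "escrow") {
    tibble::tibble(original_id = ids, second_id = unname(map[ids]))
  } else {
    NULL
  }
  list(cohort = out, key = key)
}

# run code under a temporary RNG state so package randomness never perturbs
# (or depends on) the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
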