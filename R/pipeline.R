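#' Pipeline run configuration
#'
#' Bundles everything one validation run needs: where the data come from
#' (a claims CSV, an SS-MIX2-style store, or an in-memory cohort), the code
#' lists, which definitions to apply from which sources, the adjudication
#' switches, the record-review sampling fraction, and the master seed. The
#' definition/source selection is checked here, before any data are read:
#' selecting a practice-based definition (`D4`–`D6_2`) without the claims
#' source, or the creatinine definition without the ssmix source, is a
#' configuration error.
#'
#' @param claims_path,store_path Input paths (either or both; ignored when
#'   `cohort` is given).
#' @param cohort Optional in-memory [ehr_cohort()].
#' @param code_lists Named list of [code_list()]s; defaults to
#'   [default_code_lists()], restricted to the outcomes requested.
#' @param outcomes Outcomes to validate.
#' @param def_ids Definitions to apply.
#' @param sources Data sources to use.
#' @param options An [extract_options()].
#' @param sampling_fraction Fraction of acute-renal-failure potential cases
#'   adjudicated (record review is sampled; laboratory adjudication is not).
#' @param seed Master seed for pseudonymization and sampling.
#' @param pseudonymize_mode `"irreversible"` or `"escrow"` (whether the ID
#'   correspondence table is kept).
#' @param truth Optional ground-truth tibble standing in for medical-record
#'   review (see [adjudicate_cohort()]); keyed by original patient IDs.
#' @param diabetes_mode,simultaneity,baseline_stat Adjudication switches.
#' @param window A [study_window()].
#' @param out_dir Optional directory; when set, [run_pipeline()] writes
#'   `potential_cases.csv`, `adjudications.csv`, `report.csv`, `report.txt`
#'   and `run_log.yaml` there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(claims_path = NULL, store_path = NULL, cohort = NULL,
                       code_lists = NULL,
                       outcomes = c("diabetes", "dyslipidemia",
                                    "hyperthyroidism", "acute_renal_failure"),
                       def_ids = outcome_definitions()$def_id,
                       sources = c("ssmix", "claims"),
                       options = extract_options(),
                       sampling_fraction = 0.30, seed = 1,
                       pseudonymize_mode = "irreversible", truth = NULL,
                       diabetes_mode = "mixed", simultaneity = "same_date",
                       baseline_stat = "latest",
                       window = study_window(), out_dir = NULL) {
  defs <- outcome_definitions()
  bad <- setdiff(def_ids, defs$def_id)
  if (length(bad)) {
    rlang::abort(paste0("unknown definition id(s): ",
                        paste(bad, collapse = ", ")),
                 class = "phenovalid_config_error")
  }
  for (d in def_ids) {
    if (!length(intersect(sources, definition_sources(d)))) {
      rlang::abort(sprintf(
        "definition %s requires source(s) %s, none of which are selected",
        d, paste(definition_sources(d), collapse = "/")),
        class = "phenovalid_config_error")
    }
  }
  if (is.null(cohort) && is.null(claims_path) && is.null(store_path)) {
    rlang::abort("no input: give claims_path, store_path or cohort",
                 class = "phenovalid_config_error")
  }
  code_lists <- code_lists %||% default_code_lists()
  code_lists <- code_lists[intersect(names(code_lists), outcomes)]
  structure(
    list(claims_path = claims_path, store_path = store_path,
         cohort = cohort, code_lists = code_lists, outcomes = outcomes,
         def_ids = def_ids, sources = sources, options = options,
         sampling_fraction = sampling_fraction, seed = as.integer(seed),
         pseudonymize_mode = pseudonymize_mode, truth = truth,
         diabetes_mode = diabetes_mode, simultaneity = simultaneity,
         baseline_stat = baseline_stat, window = window,
         out_dir = out_dir),
    class = "run_config")
}

#' Run the validation pipeline
#'
#' Executes the surveillance flow end to end: load (or accept) the cohort,
#' assign second patient IDs, extract potential cases under the selected
#' outcome definitions, draw the record-review sample for acute renal
#' failure, adjudicate, and assemble the validation report (plus a
#' per-stratum report for acute renal failure). Every stochastic step's
#' seed is recorded in the run log; rerunning the same configuration
#' reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return A list with `potential_cases`, `adjudications`, `report`,
#'   `report_arf_strata` (possibly empty) and `log`; files are written when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  parts <- list()
  if (!is.null(config$cohort)) {
    parts[[length(parts) + 1L]] <- config$cohort
  }
  if (!is.null(config$claims_path)) {
    parts[[length(parts) + 1L]] <-
      read_claims_table(config$claims_path, config$window)
  }
  if (!is.null(config$store_path)) {
    parts[[length(parts) + 1L]] <-
      read_ssmix_store(config$store_path, config$window)
  }
  cohort <- if (length(parts) == 1L) parts[[1]] else {
    ehr_cohort(
      diagnoses = dplyr::bind_rows(lapply(parts, `[[`, "diagnoses")),
      prescriptions = dplyr::bind_rows(lapply(parts, `[[`, "prescriptions")),
      practices = dplyr::bind_rows(lapply(parts, `[[`, "practices")),
      labs = dplyr::bind_rows(lapply(parts, `[[`, "labs")),
      window = config$window)
  }

  # second IDs; the key is kept only long enough to re-key the ground truth
  seed_pseudo <- config$seed
  ps <- pseudonymize(cohort, mode = "escrow", seed = seed_pseudo)
  cohort <- ps$cohort
  truth <- config$truth
  if (!is.null(truth)) {
    truth$patient_id <- ps$key$second_id[
      match(truth$patient_id, ps$key$original_id)]
  }
  key <- if (config$pseudonymize_mode == "escrow") ps$key else NULL
  rm(ps)

  cases <- extract_potential_cases(cohort, config$code_lists,
                                   def_ids = config$def_ids,
                                   sources = config$sources,
                                   options = config$options)

  # record-review sampling applies to the creatinine-based definition only
  seed_sample <- substream_seed(config$seed, 999L)
  arf <- cases[cases$def_id == "M2_D1", , drop = FALSE]
  subjects <- if (nrow(arf)) {
    sample_subjects(arf, config$sampling_fraction, seed_sample)
  } else {
    arf
  }
  to_adjudicate <- dplyr::bind_rows(
    cases[cases$def_id != "M2_D1", , drop = FALSE], subjects)

  adjudications <- adjudicate_cohort(
    to_adjudicate, cohort, truth = truth,
    diabetes_mode = config$diabetes_mode,
    simultaneity = config$simultaneity,
    baseline_stat = config$baseline_stat)

  potential_counts <- dplyr::count(cases, .data$outcome, .data$def_id,
                                   .data$source, name = "A")
  report <- build_report(adjudications,
                         potential_counts = potential_counts)

  arf_adj <- adjudications[adjudications$def_id == "M2_D1", , drop = FALSE]
  report_arf <- if (nrow(arf_adj)) {
    # the stratum needs only laboratory data, so the full potential-case
    # count per stratum is known even though only the sample was reviewed
    cre <- cohort$labs[cohort$labs$item == "Cre", , drop = FALSE]
    cre_by <- split(seq_len(nrow(cre)), cre$patient_id)
    arf$stratum <- vapply(seq_len(nrow(arf)), function(i) {
      stratify_prior_cre(cre[cre_by[[arf$patient_id[i]]] %||% integer(), ,
                             drop = FALSE],
                         arf$index_month[i], config$baseline_stat)
    }, character(1))
    strata_counts <- dplyr::count(arf, .data$outcome, .data$def_id,
                                  .data$source, .data$stratum, name = "A")
    build_report(arf_adj,
                 grouping = c("outcome", "def_id", "source", "stratum"),
                 potential_counts = strata_counts)
  } else {
    arf_adj
  }

  log <- list(
    n_patients = length(cohort_patient_ids(cohort)),
    n_potential_cases = nrow(cases),
    n_adjudicated = nrow(adjudications),
    seed = config$seed, seed_pseudonymize = seed_pseudo,
    seed_sampling = seed_sample,
    sampling_fraction = config$sampling_fraction,
    def_ids = config$def_ids, sources = config$sources,
    window = c(as.character(config$window$start),
               as.character(config$window$end)))

  out <- list(potential_cases = cases, subjects = subjects,
              adjudications = adjudications, report = report,
              report_arf_strata = report_arf, key = key, log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cases, file.path(config$out_dir, "potential_cases.csv"),
                     progress = FALSE)
    readr::write_csv(adjudications,
                     file.path(config$out_dir, "adjudications.csv"),
                     progress = FALSE)
    readr::write_csv(report, file.path(config$out_dir, "report.csv"),
                     progress = FALSE)
    lines <- render_report(report)
    if (nrow(arf_adj)) {
      lines <- c(lines, "", render_report(report_arf))
    }
    readr::write_lines(lines, file.path(config$out_dir, "report.txt"))
    yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  }
  out
}
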