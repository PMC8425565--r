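#' Synthetic cohort configuration
#'
#' Assembles the generator parameters from the packaged default
#' configuration file (see
#' `system.file("extdata", "default_cohort_config.yaml", package = "phenovalid")`,
#' which documents every knob) plus the arguments here. The generator
#' emulates the structure a coded-outcome validation study assumes:
#' imperfect disease coding (sensitivity for cases, a false-positive coding
#' rate for non-cases), month-level treatment/practice lags, and laboratory
#' values drawn from case / non-case distributions.
#'
#' @param n_patients Number of patients.
#' @param seed Integer master seed; all randomness flows from it through
#'   named substreams (coding, lags, labs, dates) so components are
#'   independently reproducible.
#' @param outcomes Outcomes to generate; default all four.
#' @param target_ppv Optional named numeric vector (per outcome) giving a
#'   target "disease name only" PPV in (0, 1); the non-case false-positive
#'   coding rate is back-solved to hit it, holding prevalence and
#'   sensitivity fixed (see [solve_false_positive_rate()]).
#' @param noise_scale Multiplier on every laboratory sd and jitter; `0`
#'   makes lab values deterministic at their means.
#' @param window A [study_window()].
#' @param config_file YAML parameter file; defaults to the packaged one.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2000, seed = 1,
                          outcomes = c("diabetes", "dyslipidemia",
                                       "hyperthyroidism",
                                       "acute_renal_failure"),
                          target_ppv = NULL, noise_scale = 1,
                          window = study_window(),
                          config_file = NULL) {
  config_file <- config_file %||%
    system.file("extdata", "default_cohort_config.yaml",
                package = "phenovalid", mustWork = TRUE)
  defaults <- yaml::read_yaml(config_file)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  oc <- defaults$outcomes[outcomes]
  if (any(vapply(oc, is.null, TRUE))) {
    rlang::abort("outcome missing from the configuration file",
                 class = "phenovalid_config_error")
  }
  for (nm in names(target_ppv)) {
    if (!nm %in% names(oc)) {
      rlang::abort(paste0("target_ppv names an ungenerated outcome: ", nm),
                   class = "phenovalid_config_error")
    }
    oc[[nm]]$false_positive_rate <- solve_false_positive_rate(
      oc[[nm]]$prevalence, oc[[nm]]$sensitivity, target_ppv[[nm]])
    oc[[nm]]$target_ppv <- target_ppv[[nm]]
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         window = window, noise_scale = noise_scale,
         suspected_extra_rate = defaults$suspected_extra_rate,
         lag_rx_probs = defaults$lag_rx_probs,
         lag_px_probs = defaults$lag_px_probs,
         outcomes = oc),
    class = "cohort_config")
}

#' Back-solve the false-positive coding rate for a target PPV
#'
#' Under the coding model, the expected "disease name only" PPV is
#' `prev * sens / (prev * sens + (1 - prev) * f)` where `f` is the
#' probability a non-case attracts the disease code. The map from `f` to PPV
#' is monotone decreasing, so the `f` hitting a target PPV is found by
#' bisection on `[0, 1]`.
#'
#' @param prevalence,sensitivity Coding-model parameters in (0, 1].
#' @param target_ppv Target PPV in (0, 1).
#' @param tol Bisection tolerance.
#' @return The false-positive coding rate.
#' @export
solve_false_positive_rate <- function(prevalence, sensitivity, target_ppv,
                                      tol = 1e-12) {
  if (target_ppv <= 0 || target_ppv >= 1) {
    rlang::abort("target_ppv must lie strictly in (0, 1)",
                 class = "phenovalid_config_error")
  }
  forward <- function(f) {
    prevalence * sensitivity / (prevalence * sensitivity +
                                  (1 - prevalence) * f)
  }
  if (forward(1) > target_ppv) {
    rlang::abort(sprintf(
      "target_ppv %.3f is unreachable: even certain miscoding gives PPV %.3f",
      target_ppv, forward(1)), class = "phenovalid_config_error")
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (forward(mid) > target_ppv) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-patient disease status at the configured prevalence, plants
#' coded diagnoses (with imperfect sensitivity and specificity, an optional
#' extra suspected-only diagnosis), prescriptions and practice items lagging
#' the diagnosis by whole months, and laboratory trajectories from the
#' case / non-case distributions; acute-renal-failure patients receive
#' creatinine series built by [generate_arf_series()]. The same clinical
#' content is carried in both dialects: every coded diagnosis/prescription
#' appears with `source = "claims"` and `source = "ssmix"`, practice items
#' are claims-only and laboratory results ssmix-only, mirroring what each
#' real source records.
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort` (an [ehr_cohort()]), `truth` (tibble
#'   `patient_id`, `outcome`, `is_case`, `rule_positive`, `onset_month`),
#'   `plan` (the generator's bookkeeping of planted events, usable as an
#'   extraction oracle) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  ids <- if (n > 0) sprintf("P%06d", seq_len(n)) else character()
  dx <- list(); rx <- list(); px <- list(); labs <- list()
  truth <- list(); plan <- list()
  codes <- default_code_lists()

  for (i in seq_along(config$outcomes)) {
    oc_name <- names(config$outcomes)[i]
    oc <- config$outcomes[[i]]
    part <- if (oc_name == "acute_renal_failure") {
      generate_outcome_arf(ids, oc_name, oc, config, codes[[oc_name]],
                           base_k = 100L * i)
    } else {
      generate_outcome_method1(ids, oc_name, oc, config, codes[[oc_name]],
                               base_k = 100L * i)
    }
    dx[[i]] <- part$dx; rx[[i]] <- part$rx; px[[i]] <- part$px
    labs[[i]] <- part$labs; truth[[i]] <- part$truth; plan[[i]] <- part$plan
  }

  cohort <- ehr_cohort(
    diagnoses = dplyr::bind_rows(dx), prescriptions = dplyr::bind_rows(rx),
    practices = dplyr::bind_rows(px), labs = dplyr::bind_rows(labs),
    window = config$window)
  list(cohort = cohort, truth = dplyr::bind_rows(truth),
       plan = dplyr::bind_rows(plan), config = config)
}

# both-dialect materialisation of planted coded events
both_sources <- function(tbl) {
  dplyr::bind_rows(dplyr::mutate(tbl, source = "claims"),
                   dplyr::mutate(tbl, source = "ssmix"))
}

sample_disease_code <- function(codes, n) {
  k <- sample.int(nrow(codes$disease_codes), n, replace = TRUE)
  codes$disease_codes[k, , drop = FALSE]
}

# one random day per row between the first day of each row's month and the
# window end
random_dates_in <- function(from_mi, to_date) {
  from <- as.Date(paste0(month_label(from_mi), "-01"))
  span <- pmax(as.integer(to_date - from), 27L)
  from + floor(stats::runif(length(from)) * (span + 1L))
}

generate_outcome_method1 <- function(ids, oc_name, oc, config, codes,
                                     base_k) {
  n <- length(ids)
  w <- config$window
  empty <- empty_cohort_tables()
  if (n == 0L) {
    return(list(dx = empty$diagnoses, rx = empty$prescriptions,
                px = empty$practices, labs = empty$labs,
                truth = tibble::tibble(), plan = tibble::tibble()))
  }

  # -- coding substream: disease status, coded flags, suspected extras
  cd <- with_local_seed(substream_seed(config$seed, base_k + 1L), {
    is_case <- stats::runif(n) < oc$prevalence
    coded <- ifelse(is_case, stats::runif(n) < oc$sensitivity,
                    stats::runif(n) < oc$false_positive_rate)
    has_rx_given_dx <- stats::runif(n) <
      ifelse(is_case, oc$rx_given_case, oc$rx_given_noncase)
    rx_alone <- stats::runif(n) <
      ifelse(is_case, oc$rx_alone_case, oc$rx_alone_noncase)
    has_px_dx <- stats::runif(n) < oc$px_given_dx
    has_px_rx <- stats::runif(n) < oc$px_at_rx
    suspected_extra <- stats::runif(n) < config$suspected_extra_rate
    code_rows <- sample_disease_code(codes, n)
    drug <- sample(codes$drug_codes, n, replace = TRUE)
    practice <- sample(codes$practice_codes, n, replace = TRUE)
    list(is_case = is_case, coded = coded,
         has_rx_given_dx = has_rx_given_dx, rx_alone = rx_alone,
         has_px_dx = has_px_dx, has_px_rx = has_px_rx,
         suspected_extra = suspected_extra, code_rows = code_rows,
         drug = drug, practice = practice)
  })

  # -- dates substream: onset / coding months
  mi <- with_local_seed(substream_seed(config$seed, base_k + 4L), {
    onset <- sample(seq(w$start_mi, w$end_mi), n, replace = TRUE)
    susp <- sample(seq(w$start_mi, w$end_mi), n, replace = TRUE)
    list(onset = onset, susp = susp)
  })

  # -- lags substream
  lag <- with_local_seed(substream_seed(config$seed, base_k + 2L), {
    list(
      rx = sample(seq_along(config$lag_rx_probs) - 1L, n, replace = TRUE,
                  prob = config$lag_rx_probs),
      px = sample(seq_along(config$lag_px_probs) - 1L, n, replace = TRUE,
                  prob = config$lag_px_probs)
    )
  })

  coded <- cd$coded
  dx_mi <- ifelse(coded, mi$onset, NA_integer_)
  rx_mi <- ifelse(coded & cd$has_rx_given_dx,
                  pmin(mi$onset + lag$rx, w$end_mi), NA_integer_)
  rx_mi <- ifelse(!coded & cd$rx_alone, mi$onset, rx_mi)
  px_dx_mi <- ifelse(coded & cd$has_px_dx,
                     pmin(mi$onset + lag$px, w$end_mi), NA_integer_)
  px_rx_mi <- ifelse(!is.na(rx_mi) & coded & cd$has_px_rx, rx_mi,
                     NA_integer_)

  dx_rows <- which(coded)
  dx <- both_sources(tibble::tibble(
    patient_id = ids[dx_rows], month = month_label(dx_mi[dx_rows]),
    icd10 = cd$code_rows$icd10[dx_rows],
    claim_code = cd$code_rows$claim_code[dx_rows], suspected = FALSE))
  sus_rows <- which(cd$suspected_extra)
  if (length(sus_rows)) {
    dx <- dplyr::bind_rows(dx, both_sources(tibble::tibble(
      patient_id = ids[sus_rows], month = month_label(mi$susp[sus_rows]),
      icd10 = cd$code_rows$icd10[sus_rows],
      claim_code = cd$code_rows$claim_code[sus_rows], suspected = TRUE)))
  }
  rx_rows <- which(!is.na(rx_mi))
  rx <- both_sources(tibble::tibble(
    patient_id = ids[rx_rows], month = month_label(rx_mi[rx_rows]),
    yj_code = paste0(cd$drug[rx_rows], "01001")))
  px_tbl <- dplyr::bind_rows(
    tibble::tibble(patient_id = ids[which(!is.na(px_dx_mi))],
                   month = month_label(px_dx_mi[!is.na(px_dx_mi)]),
                   practice_code = cd$practice[which(!is.na(px_dx_mi))]),
    tibble::tibble(patient_id = ids[which(!is.na(px_rx_mi))],
                   month = month_label(px_rx_mi[!is.na(px_rx_mi)]),
                   practice_code = cd$practice[which(!is.na(px_rx_mi))]))
  px_tbl$source <- rep("claims", nrow(px_tbl))

  # -- labs substream: panels for cases and coded non-cases
  labs <- with_local_seed(substream_seed(config$seed, base_k + 3L), {
    gen_panels <- function(rows, model, n_panels) {
      if (!length(rows)) return(empty_cohort_tables()$labs)
      pid <- rep(ids[rows], each = n_panels)
      from_mi <- rep(mi$onset[rows], each = n_panels)
      date <- random_dates_in(from_mi, w$end)
      out <- lapply(names(model), function(item) {
        m <- model[[item]]
        tibble::tibble(
          patient_id = pid, date = date, item = item,
          value = pmax(stats::rnorm(length(pid), m[[1]],
                                    m[[2]] * config$noise_scale), 0.001),
          unit = unname(lab_unit_table()[item]))
      })
      dplyr::bind_rows(out)
    }
    dplyr::bind_rows(
      gen_panels(which(cd$is_case), oc$labs$case, oc$n_panels_case),
      gen_panels(which(!cd$is_case & coded), oc$labs$noncase,
                 oc$n_panels_noncase))
  })

  list(
    dx = dx, rx = rx, px = px_tbl, labs = labs,
    truth = tibble::tibble(
      patient_id = ids, outcome = oc_name, is_case = cd$is_case,
      rule_positive = NA,
      onset_month = ifelse(cd$is_case, month_label(mi$onset),
                           NA_character_)),
    plan = tibble::tibble(
      patient_id = ids, outcome = oc_name, is_case = cd$is_case,
      coded = coded,
      dx_month = ifelse(is.na(dx_mi), NA_character_, month_label(dx_mi)),
      rx_month = ifelse(is.na(rx_mi), NA_character_, month_label(rx_mi)),
      px_dx_month = ifelse(is.na(px_dx_mi), NA_character_,
                           month_label(px_dx_mi)),
      px_rx_month = ifelse(is.na(px_rx_mi), NA_character_,
                           month_label(px_rx_mi)))
  )
}

#' Generate one patient's creatinine series
#'
#' Builds a serum-creatinine trajectory around an index month: two baseline
#' observations in the three months before it, with the baseline value drawn
#' inside the requested prior-Cre stratum, then follow-up observations in
#' the evaluation window (index month +/- 1). For `is_case = TRUE` a
#' qualifying acute elevation (rise >= 0.3 mg/dL over baseline) is planted
#' inside the window, so [detect_acute_cre_elevation()] fires by
#' construction; otherwise the follow-ups fluctuate tightly around baseline,
#' below both the absolute and the ratio branch for any baseline the strata
#' admit, so the rule cannot fire.
#'
#' @param config A [cohort_config()] (supplies the noise scale).
#' @param index_month `"YYYY-MM"`; must sit at least 3 months after the
#'   window start and 1 before its end.
#' @param is_case Should the series contain a qualifying elevation?
#' @param baseline_stratum `"<=1.2"`, `"(1.2,2.0]"` or `">2.0"`.
#' @param patient_id Identifier stamped on the rows.
#' @return A labs tibble (`patient_id`, `date`, `item`, `value`, `unit`).
#' @export
generate_arf_series <- function(config, index_month, is_case,
                                baseline_stratum = "<=1.2",
                                patient_id = "P000001") {
  rng <- switch(baseline_stratum,
    "<=1.2" = c(0.60, 1.15), "(1.2,2.0]" = c(1.25, 1.95),
    ">2.0" = c(2.10, 3.40),
    rlang::abort(paste0("unknown stratum: ", baseline_stratum),
                 class = "phenovalid_config_error"))
  ns <- config$noise_scale
  idx <- month_index(index_month)
  b <- stats::runif(1, rng[1], rng[2])
  jitter <- function(lo, hi) {
    mid <- (lo + hi) / 2
    mid + (stats::runif(1, lo, hi) - mid) * ns
  }
  base_dates <- as.Date(paste0(month_label(c(idx - 3L, idx - 2L)), "-10")) +
    sample.int(10L, 2L)
  base_vals <- pmin(pmax(b + c(jitter(-0.04, 0.04), jitter(-0.04, 0.04)),
                         rng[1]), rng[2])
  obs_date <- as.Date(paste0(index_month, "-05")) + sample.int(14L, 2L) - 1L
  obs_date <- sort(obs_date)
  obs_vals <- if (is_case) {
    base_vals[2] + c(stats::runif(1, 0.35, 1.20),
                     stats::runif(1, 0.35, 1.20))
  } else {
    base_vals[2] + c(jitter(-0.08, 0.12), jitter(-0.08, 0.12))
  }
  tibble::tibble(
    patient_id = patient_id,
    date = c(base_dates, obs_date),
    item = "Cre",
    value = round(pmax(c(base_vals, obs_vals), 0.05), 3),
    unit = "mg/dL")
}

generate_outcome_arf <- function(ids, oc_name, oc, config, codes, base_k) {
  n <- length(ids)
  w <- config$window
  empty <- empty_cohort_tables()
  if (n == 0L) {
    return(list(dx = empty$diagnoses, rx = empty$prescriptions,
                px = empty$practices, labs = empty$labs,
                truth = tibble::tibble(), plan = tibble::tibble()))
  }
  strata <- c("<=1.2", "(1.2,2.0]", ">2.0")

  cd <- with_local_seed(substream_seed(config$seed, base_k + 1L), {
    is_case <- stats::runif(n) < oc$prevalence
    coded <- ifelse(is_case, stats::runif(n) < oc$sensitivity,
                    stats::runif(n) < oc$false_positive_rate)
    stratum <- ifelse(
      is_case,
      sample(strata, n, replace = TRUE, prob = oc$stratum_probs_case),
      sample(strata, n, replace = TRUE, prob = oc$stratum_probs_noncase))
    rule_pos_rate <- unlist(oc$rule_positive_noncase)[stratum]
    rule_positive <- ifelse(is_case, TRUE,
                            coded & stats::runif(n) < rule_pos_rate)
    tested <- is_case | (coded & (rule_positive |
                                    stats::runif(n) < oc$cre_tested_noncase))
    code_rows <- sample_disease_code(codes, n)
    list(is_case = is_case, coded = coded, stratum = stratum,
         rule_positive = rule_positive, tested = tested,
         code_rows = code_rows)
  })

  mi <- with_local_seed(substream_seed(config$seed, base_k + 4L), {
    sample(seq(w$start_mi + 3L, w$end_mi - 1L), n, replace = TRUE)
  })

  dx_rows <- which(cd$coded)
  dx <- both_sources(tibble::tibble(
    patient_id = ids[dx_rows], month = month_label(mi[dx_rows]),
    icd10 = cd$code_rows$icd10[dx_rows],
    claim_code = cd$code_rows$claim_code[dx_rows], suspected = FALSE))

  labs <- with_local_seed(substream_seed(config$seed, base_k + 3L), {
    series <- lapply(which(cd$tested), function(j) {
      generate_arf_series(config, month_label(mi[j]),
                          is_case = cd$rule_positive[j],
                          baseline_stratum = cd$stratum[j],
                          patient_id = ids[j])
    })
    dplyr::bind_rows(series)
  })

  list(
    dx = dx, rx = empty$prescriptions, px = empty$practices, labs = labs,
    truth = tibble::tibble(
      patient_id = ids, outcome = oc_name, is_case = cd$is_case,
      rule_positive = cd$rule_positive,
      onset_month = ifelse(cd$is_case, month_label(mi), NA_character_)),
    plan = tibble::tibble(
      patient_id = ids, outcome = oc_name, is_case = cd$is_case,
      coded = cd$coded,
      dx_month = ifelse(cd$coded, month_label(mi), NA_character_),
      rx_month = NA_character_, px_dx_month = NA_character_,
      px_rx_month = NA_character_,
      stratum = cd$stratum, rule_positive = cd$rule_positive,
      tested = cd$tested)
  )
}

#' Write a generated cohort's exports
#'
#' Serialises a [generate_cohort()] result as the two dialects a validation
#' pipeline consumes — `claims.csv` and an SS-MIX2-style `store/` tree —
#' plus `ground_truth.csv` and the resolved configuration as
#' `cohort_config.yaml`.
#'
#' @param generated A list from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_exports <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_claims_table(generated$cohort, file.path(dir, "claims.csv"))
  write_ssmix_store(generated$cohort, file.path(dir, "store"))
  readr::write_csv(generated$truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  cfg <- generated$config
  yaml::write_yaml(
    list(n_patients = cfg$n_patients, seed = cfg$seed,
         noise_scale = cfg$noise_scale,
         window = list(start = as.character(cfg$window$start),
                       end = as.character(cfg$window$end)),
         outcomes = cfg$outcomes),
    file.path(dir, "cohort_config.yaml"))
  invisible(dir)
}
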