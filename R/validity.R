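#' Random subject sampling for record-based adjudication
#'
#' Adjudication against medical records is expensive, so the acute-renal-
#' failure validation reviews only a simple random sample of the potential
#' cases (the original study sampled 30%). The sample size is
#' `round_half_up(fraction * N)` and the draw is without replacement,
#' deterministic under the seed.
#'
#' @param potential_cases Tibble of potential cases (one row per case).
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return The sampled subset of `potential_cases`.
#' @export
sample_subjects <- function(potential_cases, fraction = 0.30, seed) {
  if (fraction <= 0 || fraction > 1) {
    rlang::abort("sampling fraction must be in (0, 1]",
                 class = "phenovalid_config_error")
  }
  n <- nrow(potential_cases)
  if (n == 0L) return(potential_cases)
  size <- as.integer(round_half_up(fraction * n))
  keep <- with_local_seed(seed, sort(sample.int(n, size)))
  potential_cases[keep, , drop = FALSE]
}

#' Positive predictive value
#'
#' `PPV% = 100 * B / n`, where `B` counts true cases among the `n`
#' adjudicated potential cases (all of them, or the random sample when
#' adjudication used one).
#'
#' @param B True-case count.
#' @param n Adjudicated case count (> 0).
#' @return The PPV as a percentage (unrounded; display rounding is half-up
#'   to one decimal, see [format_ppv()]).
#' @export
compute_ppv <- function(B, n) {
  if (any(n <= 0)) {
    rlang::abort("PPV is undefined for n = 0",
                 class = "phenovalid_config_error")
  }
  stopifnot(all(B >= 0), all(B <= n))
  100 * B / n
}

#' Wald confidence interval for a binomial proportion
#'
#' The normal-approximation interval `p +/- z * sqrt(p(1-p)/n)` with
#' `p = B/n`, on the percentage scale, clamped to `[0, 100]`. No continuity
#' correction is applied and no alternative interval (Wilson,
#' Agresti–Coull) is substituted: Wald is the method under study. Its known
#' undercoverage at extreme `p` with small `n` is expected behaviour.
#'
#' @inheritParams compute_ppv
#' @param z Normal quantile; 1.96 for a 95% interval.
#' @return A tibble with `ci_low_pct` and `ci_high_pct` (unrounded).
#' @export
wald_ci <- function(B, n, z = 1.96) {
  if (any(n <= 0)) {
    rlang::abort("CI is undefined for n = 0",
                 class = "phenovalid_config_error")
  }
  stopifnot(all(B >= 0), all(B <= n))
  p <- B / n
  half <- z * sqrt(p * (1 - p) / n)
  tibble::tibble(
    ci_low_pct = pmax(0, 100 * (p - half)),
    ci_high_pct = pmin(100, 100 * (p + half))
  )
}

#' Format a PPV cell as printed in validation reports
#'
#' Renders `"PPV% (low–high)"` with half-up rounding to one decimal, e.g.
#' `"21.0% (20.5-21.6)"`.
#'
#' @inheritParams wald_ci
#' @param sep Separator between the CI bounds.
#' @return Character vector of formatted cells.
#' @export
format_ppv <- function(B, n, z = 1.96, sep = "-") {
  ppv <- round_half_up(compute_ppv(B, n), 1L)
  ci <- wald_ci(B, n, z)
  sprintf("%.1f%% (%.1f%s%.1f)", ppv, round_half_up(ci$ci_low_pct, 1L), sep,
          round_half_up(ci$ci_high_pct, 1L))
}

#' Assemble a validation report
#'
#' Summarises adjudicated cases into one row per grouping cell — by default
#' (outcome, definition, source), optionally adding the prior-creatinine
#' stratum — with the counts `A` (potential cases), `n_subjects`
#' (adjudicated; equals `A` unless a sample was adjudicated), `B` (true
#' cases), `C` (other cases) and the PPV with its Wald 95% CI. This is the
#' shape of a validation-study results table row.
#'
#' @param adjudications Tibble from [adjudicate_cohort()].
#' @param grouping Character vector of grouping columns; default
#'   `c("outcome", "def_id", "source")`.
#' @param potential_counts Optional tibble giving the full potential-case
#'   count `A` per grouping cell, for reports adjudicated on a sample. When
#'   omitted, `A = n_subjects`.
#' @param z Normal quantile for the CI.
#' @return A tibble of validation rows, one per cell.
#' @export
build_report <- function(adjudications,
                         grouping = c("outcome", "def_id", "source"),
                         potential_counts = NULL, z = 1.96) {
  if (!nrow(adjudications)) {
    return(tibble::tibble(outcome = character(), def_id = character(),
                          source = character(), A = integer(),
                          n_subjects = integer(), B = integer(),
                          C = integer(), ppv_pct = numeric(),
                          ci_low_pct = numeric(), ci_high_pct = numeric(),
                          ppv_display = character()))
  }
  rows <- dplyr::summarise(
    dplyr::group_by(adjudications, dplyr::across(dplyr::all_of(grouping))),
    n_subjects = dplyr::n(),
    B = sum(.data$label == "true_case"),
    C = sum(.data$label == "other_case"),
    .groups = "drop"
  )
  if (!is.null(potential_counts)) {
    key <- intersect(grouping, names(potential_counts))
    rows <- dplyr::left_join(rows, potential_counts, by = key)
    rows$A <- dplyr::coalesce(rows$A, rows$n_subjects)
  } else {
    rows$A <- rows$n_subjects
  }
  ci <- wald_ci(rows$B, rows$n_subjects, z)
  rows$ppv_pct <- compute_ppv(rows$B, rows$n_subjects)
  rows$ci_low_pct <- ci$ci_low_pct
  rows$ci_high_pct <- ci$ci_high_pct
  rows$ppv_display <- format_ppv(rows$B, rows$n_subjects, z)
  dplyr::relocate(rows, dplyr::all_of(grouping), "A", "n_subjects", "B", "C")
}

#' Recompute validation rows from printed count pairs
#'
#' Given a table of published potential-case/true-case counts, recomputes
#' the PPV and Wald 95% CI cells from the count arithmetic alone. The
#' package ships the published counts of the surveillance study it
#' reproduces under
#' `system.file("extdata", "printed_validation_counts.csv", package = "phenovalid")`,
#' including the published one-decimal strings for comparison.
#'
#' @param counts Tibble with at least `B` and either `subjects` (adjudicated
#'   sample size) or `A`; other columns are carried through.
#' @param z Normal quantile for the CI.
#' @return `counts` with `ppv_pct`, `ci_low_pct`, `ci_high_pct` (unrounded)
#'   and the formatted `ppv_display` appended. The denominator is
#'   `subjects` where present (sample-based adjudication), otherwise `A`.
#' @export
validate_from_counts <- function(counts, z = 1.96) {
  n <- if ("subjects" %in% names(counts)) {
    dplyr::coalesce(counts$subjects, counts$A)
  } else {
    counts$A
  }
  ci <- wald_ci(counts$B, n, z)
  dplyr::mutate(counts,
                n_subjects = n,
                ppv_pct = compute_ppv(counts$B, n),
                ci_low_pct = ci$ci_low_pct,
                ci_high_pct = ci$ci_high_pct,
                ppv_display = format_ppv(counts$B, n, z))
}

#' Published validation counts
#'
#' The published count cells (potential cases `A`, adjudicated `subjects`
#' where a sample was reviewed, true cases `B`, other cases `C`) of the
#' four-outcome validation study, together with the one-decimal
#' `"PPV% (low-high)"` strings as printed, for golden-arithmetic checks via
#' [validate_from_counts()].
#'
#' @return A tibble with one row per published table row.
#' @export
printed_validation_counts <- function() {
  readr::read_csv(
    system.file("extdata", "printed_validation_counts.csv",
                package = "phenovalid", mustWork = TRUE),
    col_types = readr::cols(
      outcome = readr::col_character(), def_id = readr::col_character(),
      source = readr::col_character(), stratum = readr::col_character(),
      A = readr::col_integer(), subjects = readr::col_integer(),
      B = readr::col_integer(), C = readr::col_integer(),
      ppv_printed = readr::col_character()),
    progress = FALSE)
}

#' Render a validation report as fixed-width text
#'
#' @param report Tibble from [build_report()] or [validate_from_counts()].
#' @return A character vector of lines (also printed invisibly usable with
#'   `writeLines()`).
#' @export
render_report <- function(report) {
  cols <- intersect(c("outcome", "def_id", "source", "stratum"),
                    names(report))
  label <- do.call(paste, c(report[cols], sep = " / "))
  header <- sprintf("%-52s %9s %9s %8s %8s  %s", "Definition", "Potential",
                    "Subjects", "True", "Other", "PPV (95% CI)")
  body <- sprintf("%-52s %9d %9d %8d %8d  %s",
                  label, report$A, report$n_subjects, report$B, report$C,
                  report$ppv_display)
  c(header, body)
}
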