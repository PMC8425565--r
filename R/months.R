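#' Calendar-month utilities
#'
#' Japanese claims data reason at calendar-month granularity, so all temporal
#' logic in this package runs on month indices: a month `"YYYY-MM"` maps to
#' the integer `year * 12 + (month - 1)`, and intervals in months are plain
#' differences of these indices.
#'
#' @param month Character vector of `"YYYY-MM"` months.
#' @return `month_index()` returns an integer vector; `month_label()` the
#'   inverse mapping; `date_month()` the `"YYYY-MM"` month of a `Date`.
#' @examples
#' month_index("2008-03") - month_index("2007-04") # 11 months apart
#' month_label(month_index("2009-12") + 1)
#' @name months
NULL

#' @rdname months
#' @export
month_index <- function(month) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", month)
  if (any(!ok & !is.na(month))) {
    rlang::abort(paste0(
      "malformed month(s): ",
      paste(utils::head(month[!ok & !is.na(month)], 5L), collapse = ", ")
    ), class = "phenovalid_bad_month")
  }
  yr <- as.integer(substr(month, 1L, 4L))
  mo <- as.integer(substr(month, 6L, 7L))
  yr * 12L + (mo - 1L)
}

#' @param index Integer month indices as produced by [month_index()].
#' @rdname months
#' @export
month_label <- function(index) {
  sprintf("%04d-%02d", index %/% 12L, index %% 12L + 1L)
}

#' @param date A `Date` vector.
#' @rdname months
#' @export
date_month <- function(date) {
  format(as.Date(date), "%Y-%m")
}

#' Study observation window
#'
#' The period over which events are retained and "initial" (new-onset) events
#' are defined. The default window runs from 2007-04-01 to 2011-12-31, the
#' surveillance period of the validation study this package reproduces.
#'
#' @param start,end Window bounds (`Date` or coercible strings), inclusive.
#' @return An object of class `study_window` with elements `start`, `end`,
#'   and the corresponding month indices.
#' @examples
#' w <- study_window()
#' w$start; w$end
#' @export
study_window <- function(start = "2007-04-01", end = "2011-12-31") {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end) {
    rlang::abort("study_window requires start < end",
                 class = "phenovalid_config_error")
  }
  structure(
    list(
      start = start, end = end,
      start_mi = month_index(date_month(start)),
      end_mi = month_index(date_month(end))
    ),
    class = "study_window"
  )
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("<study_window> %s .. %s (%d months)\n",
              x$start, x$end, x$end_mi - x$start_mi + 1L))
  invisible(x)
}

#' @param window A [study_window()].
#' @rdname months
#' @export
months_in_window <- function(window) {
  month_label(seq(window$start_mi, window$end_mi))
}

# round half up at `digits` decimals; base round() is round-half-even, which
# does not reproduce the printed one-decimal PPV cells
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}
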