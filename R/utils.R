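#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert calendar dates to study-day offsets
#'
#' All tables in this package store dates as integer day offsets from a common
#' study start date, so that simulated and observed records share one clock.
#'
#' @param x a `Date`, or anything `as.Date()` accepts.
#' @param study_start the epoch (`Date` or string).
#' @return integer days since `study_start`.
#' @export
as_study_day <- function(x, study_start) {
  as.integer(as.Date(x) - as.Date(study_start))
}

#' Convert study-day offsets back to calendar dates
#'
#' @param day integer day offsets.
#' @param study_start the epoch (`Date` or string).
#' @return `Date` vector.
#' @export
as_calendar_date <- function(day, study_start) {
  as.Date(study_start) + as.integer(day)
}

# calendar year of a study day
study_year <- function(day, study_start) {
  as.integer(format(as_calendar_date(day, study_start), "%Y"))
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("configuration error: %s must be probabilities in [0, 1]", what),
         call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("configuration error: %s must be nonnegative", what), call. = FALSE)
  }
  invisible(x)
}

# stable empty data.frame with given column names/types (prototype row deleted)
empty_like <- function(proto) proto[0L, , drop = FALSE]
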