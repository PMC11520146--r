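# Calendar conventions shared across the package.
#
# All included events are Saturdays, so the weekly grid is anchored on the
# first Saturday on/after the study window start (2015-01-03 for the default
# window) and week k is that Saturday plus 7k days. Time in model units is
# years = weeks / 52.1775 (the mean number of weeks in a Gregorian year), so
# exponentiated trend coefficients read directly as per-year rate ratios.

#' Weeks per year used to convert the weekly grid to years
#'
#' @format A length-one numeric, 52.1775 (365.2425 / 7).
#' @export
weeks_per_year <- 365.2425 / 7

#' First Saturday on or after a date
#'
#' @param date a `Date` (or something coercible via [as.Date()]).
#' @return a `Date`, the earliest Saturday `>= date`.
#' @examples
#' saturday_on_or_after(as.Date("2015-01-01")) # 2015-01-03
#' @export
saturday_on_or_after <- function(date) {
  date <- as.Date(date)
  # as.integer(Date) %% 7 == 2 for Saturdays (1970-01-01 was a Thursday)
  date + (2L - as.integer(date)) %% 7L
}

#' Week index of a Saturday relative to a window anchor
#'
#' @param date Saturday date(s).
#' @param window_start start of the study window; the anchor is the first
#'   Saturday on/after it (week 0).
#' @return integer week index (may be negative for dates before the anchor).
#' @export
week_index_of <- function(date, window_start) {
  anchor <- saturday_on_or_after(window_start)
  as.integer(floor(as.numeric(as.Date(date) - anchor) / 7))
}

#' Four-week seasonality level of a date
#'
#' The year is cut into thirteen blocks anchored at 1 January: levels 1-12
#' each cover 28 consecutive days of the year and level 13 absorbs the final
#' 29 (30 in leap years) days. The mapping is year-independent apart from the
#' leap-day shift.
#'
#' @param date a `Date` vector.
#' @return integer vector in 1..13.
#' @examples
#' season_index(as.Date("2020-01-03")) # 1
#' season_index(as.Date("2020-12-31")) # 13
#' @export
season_index <- function(date) {
  yday <- as.POSIXlt(as.Date(date))$yday # 0-based day of year
  pmin(yday %/% 28L, 12L) + 1L
}
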