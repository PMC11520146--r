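# Construction of the segmented interrupted time-series design.

#' Interruption configuration
#'
#' Dates delimiting the total shutdown: events are cancelled from `gap_start`
#' (inclusive) to `reopen_date` (exclusive); `reopen_date` is the first
#' Saturday with events again. Defaults are the English shutdown, 21 March
#' 2020 to 24 July 2021.
#'
#' @param gap_start first cancelled Saturday.
#' @param reopen_date first Saturday after reopening.
#' @return a list of class `interruption_config`.
#' @export
interruption_config <- function(gap_start = as.Date("2020-03-21"),
                                reopen_date = as.Date("2021-07-24")) {
  gap_start <- as.Date(gap_start); reopen_date <- as.Date(reopen_date)
  if (!gap_start < reopen_date) {
    stop("gap_start must precede reopen_date", call. = FALSE)
  }
  structure(list(gap_start = gap_start, reopen_date = reopen_date),
            class = "interruption_config")
}

#' Build the segmented ITS design for one weekly series
#'
#' One row per week with the covariates of the segmented model: `t`, time in
#' years since the window start (weeks / 52.1775), and its square `t_sq`; the
#' 13-level four-week seasonality factor `season`; the shutdown indicator
#' `lam` (1 while events are cancelled); the reopening indicator `sig` (1 from
#' `reopen_date` on); the post-reopening time `tpost` in years since
#' reopening (0 before) and its square `tpost_sq`; and `offset_log =
#' log(population / 1000)`, so the exponentiated linear predictor is a rate
#' per 1000 residents. Rows with `lam == 1` are excluded from estimation by
#' [fit_quasipoisson()] (observed counts there are exactly zero).
#'
#' @param series a weekly series (tibble with `date`, `count`, `population`;
#'   one stratum, consecutive Saturdays).
#' @param cfg an [interruption_config()].
#' @return a tibble with columns `week_index`, `date`, `count`, `t`, `t_sq`,
#'   `season`, `lam`, `sig`, `tpost`, `tpost_sq`, `offset_log`; the
#'   configuration is attached as attribute `"interruption"`.
#' @export
build_design <- function(series, cfg = interruption_config()) {
  stopifnot(inherits(cfg, "interruption_config"))
  date <- as.Date(series$date)
  if (length(date) < 2 || any(diff(date) != 7)) {
    stop("series weeks must be consecutive Saturdays", call. = FALSE)
  }
  if (length(unique(series$population)) != 1) {
    stop("population must be constant within a stratum", call. = FALSE)
  }
  if (cfg$reopen_date < date[1]) {
    stop("reopen_date precedes the series window", call. = FALSE)
  }
  t <- as.numeric(date - date[1]) / 7 / weeks_per_year
  sig <- as.integer(date >= cfg$reopen_date)
  tpost <- ifelse(sig == 1,
                  as.numeric(date - cfg$reopen_date) / 7 / weeks_per_year, 0)
  out <- tibble::tibble(
    week_index = as.integer(round(t * weeks_per_year)),
    date = date,
    count = series$count,
    t = t,
    t_sq = t^2,
    season = factor(season_index(date), levels = 1:13),
    lam = as.integer(date >= cfg$gap_start & date < cfg$reopen_date),
    sig = sig,
    tpost = tpost,
    tpost_sq = tpost^2,
    offset_log = log(series$population / 1000)
  )
  attr(out, "interruption") <- cfg
  out
}
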