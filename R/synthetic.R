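# Gamma-Poisson generator for weekly finisher counts under the segmented
# model, so the whole pipeline is testable without any download.

#' Synthetic-scenario configuration
#'
#' Full generative parameterisation of the weekly count simulator. The mean
#' follows the segmented model exactly: for week `w` at time `t` years with
#' `T` years since reopening,
#' `mu_w = population/1000 * exp(beta0 + beta1 t + beta2 t^2 +
#' sigma (beta4 + beta5 T + beta6 T^2)) * s_season(w)`,
#' forced to zero inside the shutdown gap. Counts are drawn from a
#' gamma-Poisson (negative binomial) mixture with mean `mu_w` and variance
#' `phi * mu_w` — the standard generative stand-in for a quasi-Poisson
#' variance function. Strata differ only in baseline `beta0` and population.
#'
#' @param n_weeks number of weeks (default 425, i.e. 2015-01-03 to
#'   2023-02-18).
#' @param window_start first Saturday of the window.
#' @param gap_start,reopen_date shutdown bounds.
#' @param strata tibble with columns `stratum`, `population`, `beta0`
#'   (baseline log rate per 1000 at week 0, season level 1).
#' @param beta1,beta2 pre-shutdown linear and quadratic trend (per year,
#'   per year squared, log scale).
#' @param beta4 step change at reopening (log scale).
#' @param beta5,beta6 post-reopening linear and quadratic trend change.
#' @param season_mult positive multipliers `s_1..s_13`, `s_1 = 1`.
#' @param phi dispersion (variance / mean), `>= 1`; `phi = 1` gives Poisson
#'   counts.
#' @param seed default RNG seed used by [simulate_series()].
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_weeks = 425L,
                             window_start = as.Date("2015-01-03"),
                             gap_start = as.Date("2020-03-21"),
                             reopen_date = as.Date("2021-07-24"),
                             strata = tibble::tibble(
                               stratum = "total",
                               population = 56e6,
                               beta0 = log(1)
                             ),
                             beta1 = 0, beta2 = 0, beta4 = 0,
                             beta5 = 0, beta6 = 0,
                             season_mult = rep(1, 13),
                             phi = 1, seed = 1L) {
  stopifnot(n_weeks > 0, length(season_mult) == 13, all(season_mult > 0),
            season_mult[1] == 1, phi >= 1, all(strata$population > 0))
  window_start <- saturday_on_or_after(window_start)
  gap_start <- as.Date(gap_start); reopen_date <- as.Date(reopen_date)
  if (!(gap_start < reopen_date)) {
    stop("gap_start must precede reopen_date", call. = FALSE)
  }
  structure(
    list(n_weeks = as.integer(n_weeks), window_start = window_start,
         gap_start = gap_start, reopen_date = reopen_date,
         strata = strata, beta1 = beta1, beta2 = beta2, beta4 = beta4,
         beta5 = beta5, beta6 = beta6, season_mult = season_mult,
         phi = phi, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Canonical synthetic scenario
#'
#' The default scenario used throughout the package tests: 425 weeks from
#' 2015-01-03, the English shutdown dates, dispersion 3, and effect sizes
#' whose per-year rate ratios equal the total-population point estimates of
#' the real analysis — pre-trend 1.34 and 0.98, step 0.71, trend change 0.76
#' and 1.21. Five quintile-like strata of 11.3 million residents each differ
#' only in baseline rate (0.35 to 1.50 weekly finishes per 1000 residents at
#' week 0, ordered by deprivation quintile), giving roughly 50,000 total
#' weekly finishes at the window start. Mild seasonal multipliers with a
#' late-December trough complete the parameterisation.
#'
#' @param seed default RNG seed for [simulate_series()].
#' @return a `synthetic_config`.
#' @export
make_default_scenario <- function(seed = 1L) {
  synthetic_config(
    n_weeks = 425L,
    window_start = as.Date("2015-01-03"),
    gap_start = as.Date("2020-03-21"),
    reopen_date = as.Date("2021-07-24"),
    strata = tibble::tibble(
      stratum = as.character(1:5),
      population = rep(11.3e6, 5),
      beta0 = log(c(0.35, 0.60, 0.85, 1.10, 1.50))
    ),
    beta1 = log(1.34), beta2 = log(0.98),
    beta4 = log(0.71), beta5 = log(0.76), beta6 = log(1.21),
    season_mult = c(1.00, 0.97, 0.95, 0.98, 1.02, 1.04,
                    1.05, 1.03, 1.06, 1.02, 0.95, 0.88, 0.92),
    phi = 3, seed = seed
  )
}

# True weekly means for one stratum; cf = counterfactual (no gap, no step).
stratum_means <- function(cfg, beta0, population) {
  date <- cfg$window_start + 7L * (0:(cfg$n_weeks - 1L))
  t <- (0:(cfg$n_weeks - 1L)) / weeks_per_year
  sig <- as.integer(date >= cfg$reopen_date)
  tp <- ifelse(sig == 1,
               as.numeric(date - cfg$reopen_date) / 7 / weeks_per_year, 0)
  s <- cfg$season_mult[season_index(date)]
  base <- population / 1000 * exp(beta0 + cfg$beta1 * t + cfg$beta2 * t^2) * s
  mu_cf <- base
  mu <- base * exp(sig * (cfg$beta4 + cfg$beta5 * tp + cfg$beta6 * tp^2))
  gap <- date >= cfg$gap_start & date < cfg$reopen_date
  mu[gap] <- 0
  list(date = date, mu = mu, mu_cf = mu_cf)
}

#' Simulate weekly series from a synthetic configuration
#'
#' Draws one weekly count series per stratum (plus their sum as the
#' `"total"` stratum) from the gamma-Poisson model of [synthetic_config()],
#' and returns both the series in the stratum-level schema emitted by
#' [aggregate_weekly()] and the generating truth (per-week means and the
#' no-interruption counterfactual means) for use as an oracle.
#'
#' @param cfg a `synthetic_config`.
#' @param seed RNG seed; defaults to `cfg$seed`. Identical configuration and
#'   seed give identical output.
#' @return a list with `series` (tibble: `stratum`, `week_index`, `date`,
#'   `count`, `population`, `rate_per_1000`) and `truth` (tibble: `stratum`,
#'   `week_index`, `date`, `mu`, `mu_cf`, plus the configuration as
#'   attribute `"config"`).
#' @export
simulate_series <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(as.integer(seed))
  weeks <- 0:(cfg$n_weeks - 1L)
  per_stratum <- lapply(seq_len(nrow(cfg$strata)), function(i) {
    st <- cfg$strata[i, ]
    m <- stratum_means(cfg, st$beta0, st$population)
    counts <- numeric(cfg$n_weeks)
    live <- m$mu > 0
    counts[live] <- if (cfg$phi == 1) {
      stats::rpois(sum(live), m$mu[live])
    } else {
      stats::rnbinom(sum(live), mu = m$mu[live],
                     size = m$mu[live] / (cfg$phi - 1))
    }
    list(
      series = tibble::tibble(
        stratum = st$stratum, week_index = weeks, date = m$date,
        count = counts, population = st$population,
        rate_per_1000 = counts / st$population * 1000
      ),
      truth = tibble::tibble(
        stratum = st$stratum, week_index = weeks, date = m$date,
        mu = m$mu, mu_cf = m$mu_cf
      )
    )
  })
  series <- dplyr::bind_rows(lapply(per_stratum, `[[`, "series"))
  truth <- dplyr::bind_rows(lapply(per_stratum, `[[`, "truth"))
  if (nrow(cfg$strata) > 1) {
    tot_pop <- sum(cfg$strata$population)
    total <- series |>
      dplyr::group_by(.data$week_index, .data$date) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(stratum = "total", population = tot_pop,
                    rate_per_1000 = .data$count / tot_pop * 1000)
    series <- dplyr::bind_rows(series, total[, names(series)])
    truth_tot <- truth |>
      dplyr::group_by(.data$week_index, .data$date) |>
      dplyr::summarise(mu = sum(.data$mu), mu_cf = sum(.data$mu_cf),
                       .groups = "drop") |>
      dplyr::mutate(stratum = "total")
    truth <- dplyr::bind_rows(truth, truth_tot[, names(truth)])
  }
  attr(truth, "config") <- cfg
  list(series = series, truth = truth)
}
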