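# Counterfactual extrapolation of the pre-shutdown trend and the accounting
# of lost finishes by period.

# Season multipliers exp(gamma) for levels 1..13 (level 1 is the reference)
# and their mean weighted by how often each level occurs in the design.
season_multipliers <- function(fit) {
  beta <- fit$coefficients
  g <- setNames(rep(1, 13), 1:13)
  present <- paste0("season", 2:13)
  have <- present[present %in% names(beta)]
  g[sub("season", "", have)] <- exp(beta[have])
  g
}

mean_season_multiplier <- function(fit) {
  w <- tabulate(as.integer(fit$design$season), nbins = 13)
  stats::weighted.mean(season_multipliers(fit), w)
}

# Coefficient by name, 0 when the term is absent (reduced models).
coef0 <- function(fit, name) {
  beta <- fit$coefficients
  if (name %in% names(beta)) beta[[name]] else 0
}

#' Counterfactual, trend and post-reopening predictions per week
#'
#' Extrapolates the pre-shutdown model over the whole design window as the
#' no-interruption counterfactual: `expected_count` sets the shutdown and
#' reopening indicators to zero while keeping the full seasonal effect and
#' the population offset, so pre-gap weeks reproduce the ordinary fitted
#' values exactly. `expected_trend` replaces the seasonal multiplier by its
#' mean over the 13 levels (weighted by weeks per level), i.e. the smooth
#' dotted "ignoring seasonal variation" curve; `fitted_post` applies the full
#' post-reopening terms on the same season-averaged scale (0 before
#' reopening). `shortfall` is `expected_count - observed`.
#'
#' @param fit an `its_fit` from [fit_quasipoisson()].
#' @param design optional design tibble to predict over (defaults to the
#'   design the model was fitted on; must carry the same columns).
#' @return a tibble with columns `week_index`, `date`, `observed`,
#'   `expected_count`, `expected_trend`, `fitted_post`, `shortfall`.
#' @export
predict_counterfactual <- function(fit, design = NULL) {
  stopifnot(inherits(fit, "its_fit"))
  if (is.null(design)) design <- fit$design
  smult <- season_multipliers(fit)
  savg <- mean_season_multiplier(fit)

  base <- exp(coef0(fit, "(Intercept)") + coef0(fit, "t") * design$t +
                coef0(fit, "t_sq") * design$t_sq + design$offset_log)
  expected_count <- base * smult[as.integer(design$season)]
  expected_trend <- base * savg
  post <- exp(coef0(fit, "sig") + coef0(fit, "tpost") * design$tpost +
                coef0(fit, "tpost_sq") * design$tpost_sq)
  fitted_post <- ifelse(design$sig == 1, base * savg * post, 0)

  tibble::tibble(
    week_index = design$week_index,
    date = design$date,
    observed = design$count,
    expected_count = unname(expected_count),
    expected_trend = unname(expected_trend),
    fitted_post = unname(fitted_post),
    shortfall = unname(expected_count) - design$count
  )
}

#' Default reporting periods
#'
#' The shutdown gap and the post-reopening period, half-open on the right;
#' week membership is by Saturday date.
#'
#' @param cfg an [interruption_config()].
#' @param end end of the reporting window (exclusive), default 1 March 2023.
#' @return a tibble with columns `label`, `start`, `end`.
#' @export
default_periods <- function(cfg = interruption_config(),
                            end = as.Date("2023-03-01")) {
  tibble::tibble(
    label = c("gap", "post_reopening"),
    start = c(cfg$gap_start, cfg$reopen_date),
    end = c(cfg$reopen_date, as.Date(end))
  )
}

#' Lost finishes by period
#'
#' Sums counterfactual and observed counts over the weeks of each period
#' (membership `start <= date < end`) and appends an `all periods` row equal
#' to the sum of the listed rows. `pct_decrease` is
#' `100 * difference / counterfactual_total`. Overlapping periods trigger a
#' warning (double counting in the `all periods` row).
#'
#' @param cf output of [predict_counterfactual()].
#' @param periods tibble with columns `label`, `start`, `end`; default
#'   [default_periods()].
#' @return a tibble with columns `period`, `n_weeks`, `counterfactual_total`,
#'   `observed_total`, `difference`, `pct_decrease`.
#' @export
lost_finishes <- function(cf, periods = default_periods()) {
  starts <- as.Date(periods$start); ends <- as.Date(periods$end)
  if (nrow(periods) > 1) {
    o <- order(starts)
    if (any(ends[o][-length(o)] > starts[o][-1])) {
      warning("periods overlap; the 'all periods' row double-counts",
              call. = FALSE)
    }
  }
  rows <- lapply(seq_len(nrow(periods)), function(i) {
    sel <- cf$date >= starts[i] & cf$date < ends[i]
    tibble::tibble(
      period = periods$label[i],
      n_weeks = sum(sel),
      counterfactual_total = sum(cf$expected_count[sel]),
      observed_total = sum(cf$observed[sel]),
      # summed per week so period differences are exactly additive
      difference = sum(cf$shortfall[sel])
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(
    period = "all periods",
    n_weeks = sum(out$n_weeks),
    counterfactual_total = sum(out$counterfactual_total),
    observed_total = sum(out$observed_total),
    difference = sum(out$difference)
  ))
  out$pct_decrease <- 100 * out$difference / out$counterfactual_total
  out
}

#' Average weekly shortfall over a period
#'
#' @param difference total lost finishes over the period (or a one-row
#'   period summary, from which `difference` and `n_weeks` are taken).
#' @param n_weeks number of weeks in the period (ignored when `difference`
#'   is a period-summary row).
#' @return `difference / n_weeks`.
#' @export
weekly_average_shortfall <- function(difference, n_weeks = NULL) {
  if (is.data.frame(difference)) {
    stopifnot(nrow(difference) == 1)
    n_weeks <- difference$n_weeks
    difference <- difference$difference
  }
  if (is.null(n_weeks) || n_weeks <= 0) {
    stop("n_weeks must be positive", call. = FALSE)
  }
  difference / n_weeks
}

#' Week where the post-reopening trend catches the counterfactual
#'
#' Scans Saturdays from the reopening date over a horizon and returns the
#' earliest week at which the season-averaged post-reopening trend reaches
#' the season-averaged counterfactual trend, i.e. the first `T >= 0` (years
#' since reopening) with `beta_step + beta_post_linear * T +
#' beta_post_quadratic * T^2 >= 0`. The comparison is on the trend scale
#' (seasonality cancels), so it mirrors the crossing of the smooth curves.
#'
#' @param fit an `its_fit` containing step and post-trend terms.
#' @param horizon_years how far past reopening to scan (default 5).
#' @return the Saturday `Date` of the crossover, or `NA` (`Date`) when the
#'   curves do not meet within the horizon.
#' @export
crossover_week <- function(fit, horizon_years = 5) {
  stopifnot(inherits(fit, "its_fit"))
  reopen <- fit$interruption$reopen_date
  n <- ceiling(horizon_years * weeks_per_year)
  tt <- (0:n) / weeks_per_year
  gap_log <- coef0(fit, "sig") + coef0(fit, "tpost") * tt +
    coef0(fit, "tpost_sq") * tt^2
  hit <- which(gap_log >= 0)
  if (length(hit) == 0) return(as.Date(NA))
  reopen + 7L * (hit[1] - 1L)
}
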