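# Orchestration: ingest or simulate, fit per stratum, counterfactual,
# tables, figures, manifest.

#' Assemble a pipeline run configuration
#'
#' @param input either a `synthetic_config` (the series are simulated) or a
#'   list with paths `finishers`, `imd`, `population` (and optionally `cols`
#'   column overrides) for CSV ingestion.
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed for the run.
#' @param interruption an [interruption_config()].
#' @param window_start,window_end study window (used for CSV ingestion and
#'   period reporting; the post-reopening reporting period ends at
#'   `window_end`, exclusive).
#' @param make_figures write the two figures (participation-by-stratum and
#'   counterfactual-vs-observed)?
#' @return a list of class `run_config`.
#' @export
run_config <- function(input, out_dir, seed = 1L,
                       interruption = interruption_config(),
                       window_start = as.Date("2015-01-01"),
                       window_end = as.Date("2023-03-01"),
                       make_figures = TRUE) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (!(window_start < interruption$gap_start &&
        interruption$gap_start < interruption$reopen_date &&
        interruption$reopen_date < window_end)) {
    stop("window must bracket the interruption: start < gap_start < ",
         "reopen_date < end", call. = FALSE)
  }
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 interruption = interruption, window_start = window_start,
                 window_end = window_end, make_figures = make_figures),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Ingests (or simulates) the stratum-level weekly series, fits the
#' segmented quasi-Poisson model separately for each quintile and for the
#' total population, extrapolates the counterfactual, and writes to
#' `out_dir`: `weekly_series.csv`; `rate_ratios.csv` (one row per stratum,
#' `RR (low-high)` cells) and `rate_ratios_raw.csv`; `period_summary.csv`
#' (total stratum, counterfactual vs observed by period);
#' `residual_summary.csv`; `fits.json` (coefficients, covariance, dispersion,
#' convergence per stratum); the two figures (PNG) when requested; and
#' `manifest.json` (versions, seed, configuration hash, output list).
#' Identical configuration, inputs and seed give byte-identical tabular
#' outputs.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with the series, fits, rate-ratio table,
#'   counterfactuals, period summary and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  series <- if (inherits(cfg$input, "synthetic_config")) {
    simulate_series(cfg$input, seed = cfg$seed)$series
  } else {
    areas <- load_area_table(cfg$input$imd, cfg$input$population,
                             cols = cfg$input$cols %||% list())
    fin <- readr::read_csv(cfg$input$finishers, show_col_types = FALSE)
    aggregate_weekly(fin, areas, cfg$window_start, cfg$window_end,
                     cols = cfg$input$cols %||% list())
  }

  strata <- unique(series$stratum)
  fits <- lapply(stats::setNames(strata, strata), function(s) {
    one <- series[series$stratum == s, , drop = FALSE]
    fit_quasipoisson(build_design(one, cfg$interruption))
  })

  rr <- rate_ratio_table(fits)
  rr_wide <- format_rr_table(rr)
  cfs <- lapply(fits, predict_counterfactual)
  periods <- default_periods(cfg$interruption, end = cfg$window_end)
  summary_tot <- lost_finishes(cfs[["total"]], periods)
  resid_summary <- dplyr::bind_rows(lapply(names(fits), function(s) {
    d <- residual_diagnostics(fits[[s]])$summary
    tibble::tibble(stratum = s, mean_pearson = d$mean_pearson,
                   lag1_autocorrelation = d$lag1_autocorrelation,
                   dispersion = d$dispersion)
  }))

  paths <- file.path(cfg$out_dir, c(
    series = "weekly_series.csv", rr = "rate_ratios.csv",
    rr_raw = "rate_ratios_raw.csv", periods = "period_summary.csv",
    resid = "residual_summary.csv", fits = "fits.json",
    manifest = "manifest.json"
  ))
  names(paths) <- c("series", "rr", "rr_raw", "periods", "resid", "fits",
                    "manifest")
  readr::write_csv(series, paths[["series"]])
  readr::write_csv(rr_wide, paths[["rr"]])
  readr::write_csv(rr, paths[["rr_raw"]])
  readr::write_csv(summary_tot, paths[["periods"]])
  readr::write_csv(resid_summary, paths[["resid"]])
  jsonlite::write_json(
    lapply(fits, function(f) list(
      coefficients = as.list(f$coefficients),
      vcov = unclass(f$vcov), dispersion = f$dispersion,
      n_obs = f$n_obs, converged = f$converged
    )),
    paths[["fits"]], auto_unbox = TRUE, digits = NA
  )

  figures <- character(0)
  if (isTRUE(cfg$make_figures)) {
    f1 <- file.path(cfg$out_dir, "participation_by_stratum.png")
    f2 <- file.path(cfg$out_dir, "counterfactual_vs_observed.png")
    ggplot2::ggsave(f1, plot_participation(series),
                    width = 9, height = 5, dpi = 150)
    ggplot2::ggsave(f2, plot_counterfactual(series, fits, cfs),
                    width = 9, height = 5, dpi = 150)
    figures <- c(f1, f2)
  }

  manifest <- list(
    package = "parkrunITS",
    package_version = as.character(utils::packageVersion("parkrunITS")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    # hash of the scientific configuration only (output path excluded)
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
    n_fits = length(fits),
    fits = names(fits),
    figures = basename(figures),
    tables = basename(paths[names(paths) != "manifest"])
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(series = series, fits = fits, rate_ratios = rr,
                 rate_ratios_formatted = rr_wide, counterfactuals = cfs,
                 period_summary = summary_tot,
                 residual_summary = resid_summary, manifest = manifest,
                 paths = paths, figures = figures))
}

#' Weekly participation rates by stratum
#'
#' @param series stratum-level weekly series.
#' @return a ggplot.
#' @export
plot_participation <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = date, y = rate_per_1000,
                               colour = stratum)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "weekly finishes per 1000 residents",
                  colour = "IMD quintile",
                  title = "Weekly participation by deprivation quintile") +
    ggplot2::theme_minimal()
}

#' Observed rates with counterfactual and post-reopening trends
#'
#' Thin lines: observed weekly rates. Dotted: the pre-shutdown trend
#' extrapolated over the window, seasonality averaged out. Solid: the
#' post-reopening trend on the same scale.
#'
#' @param series stratum-level weekly series.
#' @param fits named list of `its_fit` (one per stratum).
#' @param cfs named list of counterfactual tibbles (defaults to computing
#'   them from `fits`).
#' @return a ggplot.
#' @export
plot_counterfactual <- function(series, fits, cfs = NULL) {
  if (is.null(cfs)) cfs <- lapply(fits, predict_counterfactual)
  lines <- dplyr::bind_rows(lapply(names(cfs), function(s) {
    pop <- series$population[series$stratum == s][1]
    cf <- cfs[[s]]
    tibble::tibble(
      stratum = s, date = cf$date,
      counterfactual = cf$expected_trend / pop * 1000,
      post_trend = ifelse(cf$fitted_post > 0, cf$fitted_post / pop * 1000,
                          NA_real_)
    )
  }))
  ggplot2::ggplot(series, ggplot2::aes(x = date, colour = stratum)) +
    ggplot2::geom_line(ggplot2::aes(y = rate_per_1000),
                       linewidth = 0.25, alpha = 0.6) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(y = counterfactual), linetype = "dotted",
                       linewidth = 0.7) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(y = post_trend), linewidth = 0.9,
                       na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "weekly finishes per 1000 residents",
                  colour = "IMD quintile",
                  title = "Counterfactual vs observed participation") +
    ggplot2::theme_minimal()
}
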