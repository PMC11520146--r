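# Ingestion of LSOA-level tables: deprivation, population and weekly
# finisher counts, linked and aggregated to stratum-level weekly series.

#' Load and link the area-level deprivation and population tables
#'
#' Reads the Index of Multiple Deprivation (IMD) table and the resident
#' population table, links them on the LSOA code, and returns one record per
#' area present in *both* tables. Areas missing from either table (or with a
#' missing decile/population value) are excluded, not imputed; the exclusion
#' tally is attached as the `"excluded"` attribute and reported via a message.
#' IMD deciles (1 = most deprived 10%) collapse to quintiles by
#' `ceiling(decile / 2)`. If the IMD table carries only a score, deciles are
#' derived as equal-count rank deciles of the score over areas (highest score
#' = decile 1), matching the official release convention.
#'
#' @param imd_path path to a CSV with an area-code column and an IMD decile
#'   (or score) column.
#' @param population_path path to a CSV with an area-code column and a
#'   resident-count column.
#' @param cols named list overriding default column names:
#'   `area_code`, `imd_decile`, `imd_score`, `population`.
#' @return a tibble with columns `area_code`, `imd_decile`, `imd_quintile`,
#'   `population`, plus attribute `excluded` (number of areas dropped).
#' @export
load_area_table <- function(imd_path, population_path, cols = list()) {
  cols <- utils::modifyList(
    list(area_code = "lsoa_code", imd_decile = "imd_decile",
         imd_score = "imd_score", population = "population"),
    cols
  )
  imd <- readr::read_csv(imd_path, show_col_types = FALSE)
  pop <- readr::read_csv(population_path, show_col_types = FALSE)

  require_column(imd, cols$area_code, "IMD table")
  require_column(pop, cols$area_code, "population table")
  require_column(pop, cols$population, "population table")
  if (!cols$imd_decile %in% names(imd) && !cols$imd_score %in% names(imd)) {
    stop("IMD table must carry column '", cols$imd_decile, "' or '",
         cols$imd_score, "'", call. = FALSE)
  }

  if (anyDuplicated(imd[[cols$area_code]])) {
    stop("duplicate area codes in IMD table", call. = FALSE)
  }
  if (anyDuplicated(pop[[cols$area_code]])) {
    stop("duplicate area codes in population table", call. = FALSE)
  }

  imd <- tibble::tibble(
    area_code = as.character(imd[[cols$area_code]]),
    imd_decile = if (cols$imd_decile %in% names(imd)) {
      as.integer(imd[[cols$imd_decile]])
    } else {
      score_to_decile(imd[[cols$imd_score]])
    }
  )
  pop <- tibble::tibble(
    area_code = as.character(pop[[cols$area_code]]),
    population = as.numeric(pop[[cols$population]])
  )

  linked <- dplyr::inner_join(imd, pop, by = "area_code")
  usable <- !is.na(linked$imd_decile) & !is.na(linked$population) &
    linked$population > 0
  out <- linked[usable, , drop = FALSE]
  if (any(out$imd_decile < 1L | out$imd_decile > 10L)) {
    stop("IMD deciles must lie in 1..10", call. = FALSE)
  }
  out$imd_quintile <- decile_to_quintile(out$imd_decile)
  out <- out[, c("area_code", "imd_decile", "imd_quintile", "population")]

  n_total <- length(union(imd$area_code, pop$area_code))
  excluded <- n_total - nrow(out)
  if (excluded > 0) {
    message(excluded, " of ", n_total,
            " areas excluded (missing IMD or population linkage)")
  }
  attr(out, "excluded") <- excluded
  out
}

#' Collapse IMD deciles to quintiles
#'
#' @param decile integer vector in 1..10 (1 = most deprived).
#' @return integer quintile in 1..5 (1 = most deprived 20%).
#' @export
decile_to_quintile <- function(decile) {
  as.integer(ceiling(decile / 2))
}

# Equal-count rank deciles of an IMD score; highest score = most deprived
# = decile 1, per the official Indices of Deprivation convention.
score_to_decile <- function(score) {
  score <- as.numeric(score)
  out <- rep(NA_integer_, length(score))
  ok <- !is.na(score)
  out[ok] <- as.integer(dplyr::ntile(dplyr::desc(score[ok]), 10))
  out
}

require_column <- function(df, col, what) {
  if (!col %in% names(df)) {
    stop(what, " is missing required column '", col, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Participation rate per 1000 residents
#'
#' @param count non-negative finish count(s).
#' @param population positive resident count(s).
#' @return `count / population * 1000`.
#' @examples
#' participation_rate(50, 25000) # 2
#' @export
participation_rate <- function(count, population) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  count / population * 1000
}

#' Aggregate per-area weekly finisher counts to stratum-level weekly series
#'
#' Sums weekly finisher counts over the member areas of each IMD quintile and
#' over all areas (`"total"`), on a consecutive Saturday-anchored weekly grid
#' spanning `[start, end]`. Weeks with no rows in the extract are zero-filled
#' (the shutdown gap is genuinely zero); a per-stratum tally of zero-filled
#' weeks is attached as attribute `"zero_filled"` so accidental data holes
#' stay visible. Rows dated outside the window are discarded. The population
#' denominator is the (time-constant) sum of member-area populations.
#'
#' @param finisher_table data frame of per-area weekly counts.
#' @param areas area table from [load_area_table()].
#' @param start,end window bounds (`Date` or coercible); `start <= end`.
#' @param unmatched what to do with finisher rows whose area code is absent
#'   from `areas`: `"warn"` (drop with a warning, default) or `"error"`.
#' @param cols named list overriding default finisher-table column names:
#'   `area_code`, `date`, `count`.
#' @return a tibble of weekly series, columns `stratum` (`"1"`..`"5"`,
#'   `"total"`), `week_index`, `date`, `count`, `population`,
#'   `rate_per_1000`.
#' @export
aggregate_weekly <- function(finisher_table, areas, start, end,
                             unmatched = c("warn", "error"),
                             cols = list()) {
  unmatched <- match.arg(unmatched)
  cols <- utils::modifyList(
    list(area_code = "lsoa_code", date = "date", count = "finishers"), cols
  )
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  for (cl in unlist(cols)) require_column(finisher_table, cl, "finisher table")

  fin <- tibble::tibble(
    area_code = as.character(finisher_table[[cols$area_code]]),
    date = as.Date(finisher_table[[cols$date]]),
    count = as.numeric(finisher_table[[cols$count]])
  )
  if (any(fin$count < 0)) stop("negative finisher counts", call. = FALSE)

  missing_codes <- setdiff(fin$area_code, areas$area_code)
  if (length(missing_codes) > 0) {
    msg <- paste0(length(missing_codes),
                  " area codes in the finisher table are absent from the ",
                  "area table")
    if (unmatched == "error") stop(msg, call. = FALSE)
    warning(msg, "; their rows were dropped", call. = FALSE)
    fin <- fin[!fin$area_code %in% missing_codes, , drop = FALSE]
  }

  anchor <- saturday_on_or_after(start)
  last_week <- week_index_of(end, start)
  if (last_week < 0) stop("window contains no Saturday", call. = FALSE)
  fin$week_index <- week_index_of(fin$date, start)
  fin <- fin[fin$date >= start & fin$date <= end, , drop = FALSE]

  fin <- dplyr::left_join(
    fin, areas[, c("area_code", "imd_quintile")], by = "area_code"
  )

  strata <- c(sort(unique(as.character(areas$imd_quintile))), "total")
  grid <- tidyr::expand_grid(stratum = strata, week_index = 0:last_week)
  by_quintile <- fin |>
    dplyr::mutate(stratum = as.character(.data$imd_quintile)) |>
    dplyr::group_by(.data$stratum, .data$week_index) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  total <- fin |>
    dplyr::group_by(.data$week_index) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(stratum = "total")
  observed <- dplyr::bind_rows(by_quintile, total)

  pops <- areas |>
    dplyr::group_by(stratum = as.character(.data$imd_quintile)) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop") |>
    dplyr::bind_rows(tibble::tibble(stratum = "total",
                                    population = sum(areas$population)))

  out <- grid |>
    dplyr::left_join(observed, by = c("stratum", "week_index")) |>
    dplyr::left_join(pops, by = "stratum") |>
    dplyr::mutate(
      zero_filled = is.na(.data$count),
      count = dplyr::coalesce(.data$count, 0),
      date = anchor + 7L * .data$week_index,
      rate_per_1000 = participation_rate(.data$count, .data$population)
    ) |>
    dplyr::arrange(match(.data$stratum, c(as.character(1:5), "total")),
                   .data$week_index)

  zero_filled <- out |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_zero_filled = sum(.data$zero_filled), .groups = "drop")
  out$zero_filled <- NULL
  out <- out[, c("stratum", "week_index", "date", "count", "population",
                 "rate_per_1000")]
  attr(out, "zero_filled") <- zero_filled
  out
}
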