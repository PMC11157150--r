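## Aggregation of categorized behaviour records into time-budget
## proportions and behaviour-specific mean-ODBA cells. One record = one
## 5-minute burst tick, so "proportion of time" is the proportion of
## records within a grouping cell.

#' Join the nearest thermal record onto behaviour records
#'
#' Each record gains the `blackglobe` (and `air_temp`) of the
#' nearest-in-time thermal record, provided the gap does not exceed
#' `tolerance_min` minutes; unmatched records are dropped and their count
#' reported.
#'
#' @param records Tibble with a `timestamp` column.
#' @param thermal Thermal series from [thermal_series()] (non-empty,
#'   time-ordered).
#' @param tolerance_min Maximum allowed join gap in minutes, default 30.
#' @return `records` with `blackglobe` and `air_temp` columns; attribute
#'   `"n_unmatched"` counts dropped records.
#' @export
join_weather <- function(records, thermal, tolerance_min = 30) {
  if (nrow(thermal) == 0L) abort("thermal series is empty")
  wt <- as.numeric(thermal$timestamp)
  rt <- as.numeric(records$timestamp)
  # nearest neighbour via findInterval on the ordered weather timestamps
  lo <- findInterval(rt, wt)
  lo_c <- pmax(lo, 1L)
  hi_c <- pmin(lo + 1L, length(wt))
  d_lo <- abs(rt - wt[lo_c]); d_hi <- abs(rt - wt[hi_c])
  nearest <- ifelse(d_lo <= d_hi, lo_c, hi_c)
  gap <- pmin(d_lo, d_hi)
  keep <- gap <= tolerance_min * 60
  out <- records[keep, ]
  out$blackglobe <- thermal$blackglobe[nearest[keep]]
  out$air_temp <- thermal$air_temp[nearest[keep]]
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    inform(sprintf("join_weather: dropped %d record(s) beyond the %g-minute tolerance",
                   n_drop, tolerance_min))
  }
  attr(out, "n_unmatched") <- n_drop
  out
}

#' Add local-time grouping fields
#'
#' Derives `hour` (local hour of day, 0-23), `month` and `date` from the
#' UTC timestamps after applying a fixed UTC offset. All upstream storage
#' is UTC; the offset is applied only here, once, so hour bins cannot
#' drift between modules.
#'
#' @param records Tibble with a `timestamp` column (UTC).
#' @param tz_offset_hours Hours to add to UTC to obtain local solar time.
#' @return `records` with `hour`, `month`, `date` columns.
#' @export
add_time_fields <- function(records, tz_offset_hours = 0) {
  local <- records$timestamp + tz_offset_hours * 3600
  records$hour <- as.integer(format(local, "%H", tz = "UTC"))
  records$month <- as.integer(format(local, "%m", tz = "UTC"))
  records$date <- as.Date(local, tz = "UTC")
  records
}

#' Restrict records to the afternoon window
#'
#' Keeps records with local hour in 12..17 (i.e. 12:00-17:59), the
#' hottest part of the day.
#'
#' @param records Tibble with an `hour` column (see [add_time_fields()]).
#' @return The afternoon subset.
#' @export
afternoon_filter <- function(records) {
  records[records$hour >= 12L & records$hour < 18L, ]
}

#' Integer blackglobe bin
#'
#' Bins blackglobe temperature to whole degrees Celsius by flooring, so
#' bin boundaries are reproducible.
#'
#' @param blackglobe Numeric vector of blackglobe temperatures.
#' @return Integer vector of 1-degree bins.
#' @export
blackglobe_bin <- function(blackglobe) as.integer(floor(blackglobe))

#' Behaviour time budgets per grouping cell
#'
#' Within every combination of the grouping keys, counts records per
#' analysis category and normalises to proportions; all 5 categories are
#' reported in every cell (zeros included) and sum to 1.
#'
#' @param records Categorized records (column `category`) carrying the
#'   key columns.
#' @param keys Character vector of grouping columns; default
#'   `c("blackglobe_bin", "hour", "month", "individual_id")`. A
#'   `blackglobe_bin` column is derived from `blackglobe` if absent.
#' @return Tidy tibble: keys, `category`, `proportion`, `n_records`
#'   (total records in the cell).
#' @export
time_budget <- function(records,
                        keys = c("blackglobe_bin", "hour", "month",
                                 "individual_id")) {
  if ("blackglobe_bin" %in% keys && !"blackglobe_bin" %in% names(records)) {
    records$blackglobe_bin <- blackglobe_bin(records$blackglobe)
  }
  records$category <- factor(records$category, levels = analysis_categories())
  out <- records |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "category"))),
                 .drop = FALSE, name = "k") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(n_records = sum(.data$k),
                  proportion = .data$k / sum(.data$k)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_records > 0) |>
    dplyr::select(-"k")
  out$category <- as.character(out$category)
  out
}

#' Behaviour-specific mean ODBA per grouping cell
#'
#' Means of per-burst ODBA per (keys, category); cells supported by fewer
#' than `min_n` recordings (default 30, i.e. 100 s of measurement) are
#' discarded, with the discard count attached.
#'
#' @inheritParams time_budget
#' @param min_n Minimum recordings per retained cell, default 30.
#' @return Tibble: keys, `category`, `mean_odba`, `n_recordings`;
#'   attribute `"n_discarded"` counts cells below `min_n`.
#' @export
mean_odba_cells <- function(records,
                            keys = c("blackglobe_bin", "hour", "month",
                                     "individual_id"),
                            min_n = 30L) {
  if ("blackglobe_bin" %in% keys && !"blackglobe_bin" %in% names(records)) {
    records$blackglobe_bin <- blackglobe_bin(records$blackglobe)
  }
  cells <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "category")))) |>
    dplyr::summarise(mean_odba = mean(.data$odba),
                     n_recordings = dplyr::n(), .groups = "drop")
  keep <- cells$n_recordings >= min_n
  out <- cells[keep, ]
  if (any(!keep)) {
    inform(sprintf("mean_odba_cells: discarded %d cell(s) with < %d recordings",
                   sum(!keep), min_n))
  }
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Diel time budgets on hot versus cool days
#'
#' Restricts the records to the selected extreme days, labels them
#' `"hot"` or `"cool"`, and aggregates time budgets over the full
#' 24-hour cycle per (day class, hour, individual).
#'
#' @param records Categorized records with `date` and `hour` columns.
#' @param extreme_days An `"extreme_days"` selection from
#'   [select_extreme_days()].
#' @return Tidy tibble: `dayclass`, `hour`, `individual_id`, `category`,
#'   `proportion`, `n_records`.
#' @export
diel_budget <- function(records, extreme_days) {
  stopifnot(inherits(extreme_days, "extreme_days"))
  hot <- records$date %in% extreme_days$hottest
  cool <- records$date %in% extreme_days$coolest
  out <- records[hot | cool, ]
  out$dayclass <- ifelse(out$date[seq_len(nrow(out))] %in% extreme_days$hottest,
                         "hot", "cool")
  time_budget(out, keys = c("dayclass", "hour", "individual_id"))
}

#' Write budget or ODBA cells as tidy delimited text
#'
#' @param cells A tibble from [time_budget()], [mean_odba_cells()] or
#'   [diel_budget()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
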