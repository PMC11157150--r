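## Blackglobe heat index, daily maxima and hottest/coolest-day selection.

#' Default blackglobe regression coefficients
#'
#' The blackglobe temperature — an integrative heat-stress index — is
#' estimated from standard weather-station variables with an empirical
#' linear regression
#' `Tg = intercept + a * air_temp + b * solar + c * rh`.
#' The default coefficients are this package's own calibration for a
#' dryland summer regime (globe roughly 15 C above air at midday under
#' ~40 C air and full sun); they keep the globe at or above air
#' temperature whenever the sun is up. Site-specific coefficients should
#' be supplied via configuration when available.
#'
#' @return Named list `intercept`, `air_temp`, `solar`, `rh`.
#' @export
blackglobe_coefficients <- function() {
  list(intercept = 0.5, air_temp = 1.35, solar = 0.006, rh = -0.002)
}

#' Blackglobe temperature from weather variables
#'
#' Vectorized linear estimator, monotone increasing in air temperature
#' and solar radiation at the default coefficients. Passing
#' `coefficients = "identity"` returns air temperature unchanged — a
#' clearly-labelled fallback that keeps the pipeline runnable when no
#' calibration exists.
#'
#' @param air_temp Air temperature in deg C.
#' @param solar Solar radiation in W/m2.
#' @param rh Relative humidity in percent (0..100).
#' @param coefficients Named list as in [blackglobe_coefficients()], or
#'   the string `"identity"`.
#' @return Blackglobe temperature in deg C.
#' @export
blackglobe <- function(air_temp, solar, rh,
                       coefficients = blackglobe_coefficients()) {
  if (identical(coefficients, "identity")) {
    inform("blackglobe: identity fallback in use (blackglobe = air_temp)")
    return(air_temp)
  }
  need <- c("intercept", "air_temp", "solar", "rh")
  missing_keys <- setdiff(need, names(coefficients))
  if (length(missing_keys) > 0L) {
    abort(paste0("blackglobe coefficients missing: ",
                 paste(missing_keys, collapse = ", ")))
  }
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) abort("rh must lie in [0, 100]")
  coefficients$intercept + coefficients$air_temp * air_temp +
    coefficients$solar * solar + coefficients$rh * rh
}

#' Attach blackglobe temperature to a weather series
#'
#' @param weather Weather tibble from [read_weather()].
#' @inheritParams blackglobe
#' @return The weather tibble with a `blackglobe` column.
#' @export
thermal_series <- function(weather, coefficients = blackglobe_coefficients()) {
  weather$blackglobe <- blackglobe(weather$air_temp, weather$solar,
                                   weather$rh, coefficients)
  weather
}

#' Daily maximum of a weather or thermal field
#'
#' @param series Tibble with a `timestamp` column.
#' @param field Column to maximise, default `"air_temp"`.
#' @return Tibble with one row per calendar date present: `date`, `max`.
#' @export
daily_max <- function(series, field = "air_temp") {
  if (nrow(series) == 0L) abort("daily_max needs a non-empty series")
  date <- as.Date(series$timestamp, tz = "UTC")
  agg <- tapply(series[[field]], date, max)
  tibble::tibble(date = as.Date(names(agg)), max = as.numeric(agg))
}

#' Select the hottest and coolest days by daily maximum air temperature
#'
#' Restricts the daily maxima to calendar months in `months` (default the
#' hottest months, October-December) and returns the `n` hottest and `n`
#' coolest dates. Ties are broken towards the earlier date.
#'
#' @param dmax Tibble `date`/`max` from [daily_max()].
#' @param n Number of days per extreme, default 10.
#' @param months Integer months forming the selection window, default
#'   `c(10, 11, 12)`.
#' @return List of class `"extreme_days"` with `hottest` and `coolest`
#'   date vectors (disjoint, each of length `n`) and the criterion.
#' @export
select_extreme_days <- function(dmax, n = 10L,
                                months = c(10L, 11L, 12L)) {
  win <- dmax[as.integer(format(dmax$date, "%m")) %in% months, ]
  if (nrow(win) < 2L * n) {
    abort(sprintf("need at least %d dates in the window, have %d",
                  2L * n, nrow(win)))
  }
  ord_hot <- order(-win$max, win$date)   # ties -> earlier date
  ord_cool <- order(win$max, win$date)
  structure(
    list(hottest = sort(win$date[ord_hot[seq_len(n)]]),
         coolest = sort(win$date[ord_cool[seq_len(n)]]),
         criterion = "daily max air temperature"),
    class = "extreme_days"
  )
}

#' @export
print.extreme_days <- function(x, ...) {
  cat("Extreme days by", x$criterion, "\n")
  cat("  hottest:", paste(format(x$hottest), collapse = ", "), "\n")
  cat("  coolest:", paste(format(x$coolest), collapse = ", "), "\n")
  invisible(x)
}

#' Write extreme-day selection as a dated text list
#'
#' @param extremes An `"extreme_days"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extreme_days <- function(extremes, path) {
  write.csv(data.frame(
    date = c(format(extremes$hottest), format(extremes$coolest)),
    class = rep(c("hot", "cool"),
                c(length(extremes$hottest), length(extremes$coolest)))
  ), path, row.names = FALSE)
  invisible(path)
}
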