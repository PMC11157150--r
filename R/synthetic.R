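## Synthetic data with known ground truth: labelled accelerometer bursts
## with behaviour-specific signal structure, behaviour timelines driven by
## a diel cycle and blackglobe temperature, and matching weather series.
##
## Signal models are phenomenological — a static posture vector, one
## periodic component and Gaussian noise per behaviour — the minimum
## structure that exercises every burst feature. No biomechanical realism
## is claimed. Ground-truth parameters are always returned next to the
## data so recovery tests never reach into the generator's internals.

#' Default behaviour signal models
#'
#' One model per ethogram behaviour: a static posture offset per axis
#' (centred counts; 1 G is 512 counts), a single periodic component
#' (frequency in Hz, amplitude in counts, unit axis loading) and a noise
#' standard deviation. Defaults give pairwise-distinguishable behaviours:
#' resting postures with low noise, a ~1.5 Hz surge gait for walking with
#' faster/larger gaits for trotting and running, head-down postures for
#' grazing and drinking, and low-amplitude ~1 Hz chewing on the yz-plane
#' for ruminating.
#'
#' @return Named list of signal models, one per [ethogram_labels()]
#'   behaviour, each with fields `posture`, `freq`, `amp`, `loading`,
#'   `noise_sd`.
#' @export
default_signal_models <- function() {
  m <- function(px, py, pz, freq, amp, lx, ly, lz, noise_sd) {
    l <- c(x = lx, y = ly, z = lz)
    if (sum(l^2) > 0) l <- l / sqrt(sum(l^2))
    list(posture = c(x = px, y = py, z = pz),
         freq = freq, amp = amp, loading = l, noise_sd = noise_sd)
  }
  list(
    "browsing"     = m( 200,   0, 470, 0.5,  80, 1, 0, 0,   50),
    "drinking"     = m(-450,   0, 240, 0,     0, 0, 0, 0,   25),
    "foraging"     = m(-150,   0, 480, 1.0, 130, 1, 0, 0,   60),
    "grazing"      = m(-350,   0, 370, 0.7,  90, 0.8, 0, 0.6, 70),
    "grooming"     = m(-100, 200, 450, 2.0, 120, 0.2, 0.9, 0.37, 55),
    "low-activity" = m(   0,   0, 512, 0,     0, 0, 0, 0,   15),
    "ruminating"   = m(   0,   0, 512, 1.0,  60, 0, 0.7, 0.7, 20),
    "running"      = m(   0,   0, 512, 4.5, 750, 0.8, 0.4, 0.45, 80),
    "salt-licking" = m(-300, 150, 380, 1.5,  60, 1, 0, 0,   35),
    "sleeping"     = m( 350, 260, 260, 0,     0, 0, 0, 0,    6),
    "trotting"     = m(   0,   0, 512, 3.0, 450, 0.8, 0.4, 0.45, 60),
    "walking"      = m(   0,   0, 512, 1.5, 220, 0.9, 0.3, 0.3, 40)
  )
}

## Expected tick-level ODBA per behaviour implied by a signal model
## (phenomenological: periodic amplitude plus noise contribution).
signal_odba_means <- function(models = default_signal_models()) {
  vapply(models, function(m) 0.55 * m$amp + 1.6 * m$noise_sd + 2, numeric(1))
}

#' Simulate one labelled accelerometer burst
#'
#' Counts are `clip(round(2048 + posture + periodic + noise), 0, 4095)`
#' per axis, with a random phase per burst. Deterministic per seed.
#'
#' @param behaviour Behaviour label present in `models`.
#' @param models Signal models, see [default_signal_models()].
#' @param fs Sampling frequency in Hz (default 33.3).
#' @param n Samples per axis (default 110, i.e. 3.3 s).
#' @param seed Optional integer seed.
#' @param individual_id,timestamp Metadata for the burst row.
#' @return A one-row labelled burst tibble (raw counts).
#' @export
simulate_burst <- function(behaviour, models = default_signal_models(),
                           fs = 33.3, n = 110L, seed = NULL,
                           individual_id = "sim01",
                           timestamp = as.POSIXct("2020-10-01 08:00:00",
                                                  tz = "UTC")) {
  if (!behaviour %in% names(models)) {
    abort(paste0("no signal model for behaviour '", behaviour, "'"))
  }
  if (!is.null(seed)) set.seed(seed)
  mdl <- models[[behaviour]]
  tt <- (seq_len(n) - 1L) / fs
  phase <- runif(1, 0, 2 * pi)
  axis <- function(a) {
    v <- 2048 + mdl$posture[[a]] +
      mdl$amp * mdl$loading[[a]] * sin(2 * pi * mdl$freq * tt + phase) +
      rnorm(n, 0, mdl$noise_sd)
    as.integer(pmin(pmax(round(v), 0), 4095))
  }
  tibble::tibble(individual_id = individual_id, timestamp = timestamp,
                 fs = fs, n = as.integer(n),
                 x = list(axis("x")), y = list(axis("y")), z = list(axis("z")),
                 behaviour = behaviour)
}

#' Simulate a sequence of labelled bursts
#'
#' @param behaviours Character vector of behaviour labels, one burst each.
#' @inheritParams simulate_burst
#' @param start First burst timestamp; subsequent bursts follow every
#'   `interval` seconds.
#' @param interval Seconds between burst starts (default 30, the
#'   observation-collar schedule).
#' @param seed Integer seed for the whole sequence.
#' @return A labelled burst tibble.
#' @export
simulate_bursts <- function(behaviours, models = default_signal_models(),
                            fs = 33.3, n = 110L, seed = 1L,
                            individual_id = "sim01",
                            start = as.POSIXct("2020-10-01 08:00:00",
                                               tz = "UTC"),
                            interval = 30) {
  set.seed(seed)
  rows <- lapply(seq_along(behaviours), function(i) {
    simulate_burst(behaviours[i], models, fs = fs, n = n, seed = NULL,
                   individual_id = individual_id,
                   timestamp = start + (i - 1L) * interval)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a balanced labelled training set
#'
#' @param n_per_class Bursts per behaviour (default 170, about 2000
#'   bursts over the 12-behaviour ethogram).
#' @inheritParams simulate_bursts
#' @return A labelled burst tibble in shuffled order.
#' @export
simulate_training_set <- function(n_per_class = 170L,
                                  models = default_signal_models(),
                                  seed = 1L, fs = 33.3, n = 110L) {
  behaviours <- rep(names(models), each = n_per_class)
  set.seed(seed)
  behaviours <- sample(behaviours)
  simulate_bursts(behaviours, models, fs = fs, n = n, seed = seed + 1L,
                  individual_id = "obs01")
}

#' Default temperature effects on behaviour allocation
#'
#' Log-odds slopes per degree of blackglobe temperature (relative to a
#' 45 C reference) applied to the behaviour weights of the timeline
#' generator: heat suppresses grazing and mildly suppresses browsing
#' while favouring rumination and low activity, the qualitative response
#' expected for dryland antelope.
#'
#' @return Named numeric vector over [ethogram_labels()].
#' @export
default_temperature_slopes <- function() {
  s <- setNames(numeric(length(ethogram_labels())), ethogram_labels())
  s["grazing"] <- -0.05
  s["browsing"] <- -0.01
  s["ruminating"] <- 0.03
  s["low-activity"] <- 0.04
  s
}

## Baseline hourly behaviour weights (before temperature effects):
## crepuscular grazing, diurnal browsing/foraging, nocturnal resting,
## and a ~2% pool of rare behaviours.
base_hour_weights <- function(hour) {
  daylight <- exp(-((hour - 12) / 4)^2)
  dawn <- exp(-((hour - 7) / 2.5)^2)
  dusk <- exp(-((hour - 17) / 2.5)^2)
  night <- (cos(2 * pi * (hour - 2) / 24) + 1) / 2
  c("browsing"     = 0.13 + 0.13 * daylight,
    "drinking"     = 0.006,
    "foraging"     = 0.02 + 0.03 * daylight,
    "grazing"      = 0.22 + 0.30 * (dawn + dusk),
    "grooming"     = 0.008,
    "low-activity" = 0.18 + 0.30 * night,
    "ruminating"   = 0.18 + 0.06 * night,
    "running"      = 0.002,
    "salt-licking" = 0.003,
    "sleeping"     = 0.02 * night,
    "trotting"     = 0.003,
    "walking"      = 0.10)
}

#' Build a timeline scenario configuration
#'
#' Defines the study conditions the generator emulates: a set of collared
#' individuals recording one 3.3 s burst every 5 minutes (288 ticks per
#' day) at 33.3 Hz across the hot-season months, an hourly weather series
#' with a sinusoidal diel air-temperature cycle whose daily maxima fall
#' into distinct hot and cool days, and behaviour allocation per tick
#' from a multinomial over the 12-behaviour ethogram whose weights depend
#' on hour of day and (optionally) blackglobe temperature, with
#' first-order persistence.
#'
#' @param n_individuals Number of collared individuals (default 2).
#' @param n_days Number of days (default 20, the minimum that supports
#'   10 hottest + 10 coolest day selection).
#' @param start_date First day (default `"2020-10-01"`, hot-season).
#' @param temperature_slopes Named log-odds slopes per degree blackglobe,
#'   see [default_temperature_slopes()]; zero everywhere gives a null
#'   scenario.
#' @param diel_modifier `NULL`, or a list `list(type = "compensation",
#'   amp = )` (hot days suppress daytime grazing and compensate at night,
#'   leaving the 24-h mean unchanged) or `list(type = "reduction",
#'   factor = )` (hot days scale grazing probability by `factor` at every
#'   hour). Displaced probability mass moves to low-activity.
#' @param hot_fraction Fraction of days that are hot (default 0.5).
#' @param cool_max_range,hot_max_range Ranges (deg C) from which daily
#'   maximum air temperatures are drawn for cool and hot days; defaults
#'   26-32.4 and 39.1-40.6, the hot-season spread at a dryland site.
#' @param diel_range Diel air-temperature range in deg C (default 14).
#' @param persistence Probability that a tick repeats the previous
#'   behaviour instead of a fresh multinomial draw (default 0.3).
#' @param reference_blackglobe Blackglobe reference for the temperature
#'   effect (default 45 C).
#' @param fs,n_samples,burst_interval Burst geometry: sampling frequency,
#'   samples per axis, seconds between burst starts (33.3 Hz, 110, 300).
#' @param seed Integer seed.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_individuals = 2L, n_days = 20L,
                            start_date = "2020-10-01",
                            temperature_slopes = default_temperature_slopes(),
                            diel_modifier = NULL,
                            hot_fraction = 0.5,
                            cool_max_range = c(26, 32.4),
                            hot_max_range = c(39.1, 40.6),
                            diel_range = 14,
                            persistence = 0.3,
                            reference_blackglobe = 45,
                            fs = 33.3, n_samples = 110L,
                            burst_interval = 300,
                            seed = 1L) {
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_days = as.integer(n_days),
         start_date = as.Date(start_date),
         temperature_slopes = temperature_slopes,
         diel_modifier = diel_modifier,
         hot_fraction = hot_fraction,
         cool_max_range = cool_max_range, hot_max_range = hot_max_range,
         diel_range = diel_range, persistence = persistence,
         reference_blackglobe = reference_blackglobe,
         fs = fs, n_samples = as.integer(n_samples),
         burst_interval = burst_interval, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Null scenario: behaviour allocation independent of temperature
#'
#' @param ... Passed to [scenario_config()].
#' @return A `"scenario_config"` with all temperature slopes zero and no
#'   diel modifier.
#' @export
scenario_null <- function(...) {
  slopes <- setNames(numeric(length(ethogram_labels())), ethogram_labels())
  scenario_config(temperature_slopes = slopes, diel_modifier = NULL, ...)
}

#' Diel compensation scenario
#'
#' On hot days, grazing probability is shifted by
#' `-amp * cos(2*pi*(hour - 14)/24)`: suppressed through the heat of the
#' day, boosted at night, with the 24-h mean unchanged by construction.
#'
#' @param amp Amplitude of the probability shift (default 0.12).
#' @param ... Passed to [scenario_config()].
#' @return A `"scenario_config"`.
#' @export
scenario_diel_compensation <- function(amp = 0.12, ...) {
  slopes <- setNames(numeric(length(ethogram_labels())), ethogram_labels())
  scenario_config(temperature_slopes = slopes,
                  diel_modifier = list(type = "compensation", amp = amp), ...)
}

#' Diel reduction scenario
#'
#' On hot days, grazing probability is scaled by `factor` at every hour
#' (e.g. 0.8 plants a 20% lower 24-h mean on hot days).
#'
#' @param factor Multiplicative factor on hot-day grazing probability.
#' @param ... Passed to [scenario_config()].
#' @return A `"scenario_config"`.
#' @export
scenario_diel_reduction <- function(factor = 0.8, ...) {
  slopes <- setNames(numeric(length(ethogram_labels())), ethogram_labels())
  scenario_config(temperature_slopes = slopes,
                  diel_modifier = list(type = "reduction", factor = factor),
                  ...)
}

## Hourly weather for a scenario plus the day-class assignment.
simulate_weather <- function(config) {
  days <- config$start_date + seq_len(config$n_days) - 1L
  n_hot <- round(config$n_days * config$hot_fraction)
  dayclass <- sample(rep(c("hot", "cool"),
                         c(n_hot, config$n_days - n_hot)))
  dmax <- ifelse(dayclass == "hot",
                 runif(config$n_days, config$hot_max_range[1],
                       config$hot_max_range[2]),
                 runif(config$n_days, config$cool_max_range[1],
                       config$cool_max_range[2]))
  grid <- expand.grid(hour = 0:23, day = seq_len(config$n_days))
  air <- dmax[grid$day] -
    config$diel_range * (1 - cos(2 * pi * (grid$hour - 14) / 24)) / 2
  solar <- ifelse(grid$hour >= 6 & grid$hour <= 18,
                  900 * sin(pi * (grid$hour - 6) / 12), 0)
  rh <- pmin(pmax(75 - 1.2 * air, 5), 95)
  weather <- tibble::tibble(
    timestamp = as.POSIXct(paste(days[grid$day], sprintf("%02d:00:00", grid$hour)),
                           tz = "UTC"),
    air_temp = air, solar = solar, rh = rh
  )
  list(weather = weather,
       days = tibble::tibble(date = days, dayclass = dayclass,
                             daily_max = dmax))
}

## Behaviour probabilities for one (hour, blackglobe, dayclass) state.
tick_probabilities <- function(hour, bg, dayclass, config) {
  w <- base_hour_weights(hour)
  w <- w * exp(config$temperature_slopes[names(w)] *
                 (bg - config$reference_blackglobe))
  p <- w / sum(w)
  mod <- config$diel_modifier
  if (!is.null(mod) && dayclass == "hot") {
    g <- p[["grazing"]]
    g_new <- switch(mod$type,
      compensation = g - mod$amp * cos(2 * pi * (hour - 14) / 24),
      reduction = mod$factor * g,
      abort(paste0("unknown diel modifier type '", mod$type, "'")))
    g_new <- min(max(g_new, 1e-4), 0.95)
    p[["low-activity"]] <- p[["low-activity"]] + (g - g_new)
    p[["grazing"]] <- g_new
  }
  p
}

#' Simulate a behaviour timeline with weather and ground truth
#'
#' For every individual and 5-minute tick, a behaviour is drawn from the
#' multinomial implied by hour of day and blackglobe temperature (with
#' first-order persistence); each tick also carries a burst-level ODBA
#' value drawn from a behaviour-specific gamma distribution whose means
#' are part of the ground truth. Optionally, full raw burst waveforms are
#' synthesised for every tick.
#'
#' @param config A [scenario_config()].
#' @param signals If `TRUE`, also synthesise raw tri-axial waveforms per
#'   tick and return them as a labelled burst tibble (`$bursts`).
#' @param models Signal models used for ODBA means and waveforms.
#' @return List with `ticks` (individual_id, timestamp, behaviour, odba),
#'   `weather` (hourly series), `truth` (planted parameters: temperature
#'   slopes, diel modifier, per-behaviour ODBA means, hot/cool dates) and
#'   optionally `bursts`.
#' @export
simulate_timeline <- function(config, signals = FALSE,
                              models = default_signal_models()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  wx <- simulate_weather(config)
  thermal <- thermal_series(wx$weather)
  # blackglobe lookup per (day index, hour)
  bg <- matrix(thermal$blackglobe, nrow = 24)  # hours x days
  odba_mean <- signal_odba_means(models)
  behaviours <- ethogram_labels()
  ticks_per_day <- as.integer(24 * 3600 / config$burst_interval)

  out <- vector("list", config$n_individuals)
  for (ind in seq_len(config$n_individuals)) {
    id <- sprintf("ind%02d", ind)
    n_ticks <- config$n_days * ticks_per_day
    beh <- character(n_ticks)
    prev <- NULL
    tick_hour <- integer(n_ticks)
    tick_day <- integer(n_ticks)
    k <- 0L
    for (d in seq_len(config$n_days)) {
      dayclass <- wx$days$dayclass[d]
      for (tick in seq_len(ticks_per_day)) {
        k <- k + 1L
        hour <- ((tick - 1L) * config$burst_interval) %/% 3600
        tick_hour[k] <- hour
        tick_day[k] <- d
        if (!is.null(prev) && runif(1) < config$persistence) {
          beh[k] <- prev
        } else {
          p <- tick_probabilities(hour, bg[hour + 1L, d], dayclass, config)
          beh[k] <- sample(behaviours, 1L, prob = p[behaviours])
        }
        prev <- beh[k]
      }
    }
    mu <- odba_mean[beh]
    odba_val <- rgamma(n_ticks, shape = 25, rate = 25 / mu)
    ts <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC") +
      (tick_day - 1L) * 86400 +
      (seq_len(n_ticks) - 1L) %% ticks_per_day * config$burst_interval
    out[[ind]] <- tibble::tibble(individual_id = id, timestamp = ts,
                                 behaviour = beh, odba = odba_val)
  }
  ticks <- dplyr::bind_rows(out)
  truth <- list(
    temperature_slopes = config$temperature_slopes,
    diel_modifier = config$diel_modifier,
    odba_means = odba_mean,
    reference_blackglobe = config$reference_blackglobe,
    hot_days = wx$days$date[wx$days$dayclass == "hot"],
    cool_days = wx$days$date[wx$days$dayclass == "cool"],
    persistence = config$persistence
  )
  res <- list(ticks = ticks, weather = wx$weather, truth = truth)
  if (signals) {
    res$bursts <- simulate_bursts(ticks$behaviour, models,
                                  fs = config$fs, n = config$n_samples,
                                  seed = config$seed + 1L)
    res$bursts$individual_id <- ticks$individual_id
    res$bursts$timestamp <- ticks$timestamp
  }
  res
}

#' Write a deterministic fixture suite
#'
#' Writes a labelled training set (interleaved dialect), a scenario tick
#' file or burst file, the hourly weather series and the ground-truth
#' record. Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param n_per_class Training bursts per behaviour (default 170).
#' @param config Scenario configuration; defaults to
#'   [scenario_config()] with `seed`.
#' @param signals If `TRUE` the scenario is written as raw bursts
#'   (`scenario_bursts.csv`), otherwise as behaviour ticks
#'   (`scenario_ticks.csv`).
#' @return Named character vector of written paths, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1L, n_per_class = 170L,
                               config = NULL, signals = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(config)) config <- scenario_config(seed = seed)
  dialect <- burst_dialect("interleaved", col_behaviour = "behaviour")

  train <- simulate_training_set(n_per_class, seed = seed)
  p_train <- file.path(dir, "train_bursts.csv")
  write_bursts(train, p_train, dialect)

  tl <- simulate_timeline(config, signals = signals)
  p_weather <- file.path(dir, "weather.csv")
  wx <- tl$weather
  wx$timestamp <- format(wx$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  write.csv(wx, p_weather, row.names = FALSE)

  if (signals) {
    p_scen <- file.path(dir, "scenario_bursts.csv")
    write_bursts(tl$bursts, p_scen, dialect)
  } else {
    p_scen <- file.path(dir, "scenario_ticks.csv")
    tk <- tl$ticks
    tk$timestamp <- format(tk$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    write.csv(tk, p_scen, row.names = FALSE)
  }

  p_truth <- file.path(dir, "truth.yaml")
  truth <- tl$truth
  truth$hot_days <- format(truth$hot_days)
  truth$cool_days <- format(truth$cool_days)
  truth$temperature_slopes <- as.list(truth$temperature_slopes)
  truth$odba_means <- as.list(round(truth$odba_means, 6))
  yaml::write_yaml(truth, p_truth)

  invisible(c(train = p_train, scenario = p_scen, weather = p_weather,
              truth = p_truth))
}
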