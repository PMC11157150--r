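# Shared fixtures and independent oracles for the test suite.

make_burst <- function(x, y, z, fs = 33.3, id = "b1",
                       ts = as.POSIXct("2020-10-01 12:00:00", tz = "UTC")) {
  tibble::tibble(individual_id = id, timestamp = ts, fs = fs,
                 n = length(x), x = list(as.integer(x)),
                 y = list(as.integer(y)), z = list(as.integer(z)))
}

rand_raw_burst <- function(n = 110, seed = 1, centre = 2048, sd = 200) {
  set.seed(seed)
  clip <- function(v) as.integer(pmin(pmax(round(v), 0), 4095))
  make_burst(clip(rnorm(n, centre, sd)), clip(rnorm(n, centre, sd)),
             clip(rnorm(n, centre, sd)))
}

# Brute-force running mean: explicit double loop over the nominal window
# i - floor((w-1)/2) .. i + floor(w/2), clamped to the series.
oracle_running_mean <- function(v, w) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - (w - 1L) %/% 2L)
    hi <- min(n, i + w %/% 2L)
    s <- 0
    for (j in lo:hi) s <- s + v[j]
    out[i] <- s / (hi - lo + 1L)
  }
  out
}

oracle_odba <- function(x, y, z, w) {
  dx <- x - oracle_running_mean(x, w)
  dy <- y - oracle_running_mean(y, w)
  dz <- z - oracle_running_mean(z, w)
  mean(abs(dx) + abs(dy) + abs(dz))
}

# Brute-force DFT magnitude at bins 1..floor(N/2) via explicit cos/sin
# sums (no fft).
oracle_dft_mags <- function(v) {
  v <- v - mean(v)
  n <- length(v)
  t <- 0:(n - 1)
  vapply(seq_len(n %/% 2), function(k) {
    re <- sum(v * cos(2 * pi * k * t / n))
    im <- -sum(v * sin(2 * pi * k * t / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

oracle_entropy <- function(v) {
  mags <- oracle_dft_mags(v)
  p <- mags / sum(mags)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(mags))
}

rotate_yz <- function(y, z, theta) {
  list(y = cos(theta) * y - sin(theta) * z,
       z = sin(theta) * y + cos(theta) * z)
}

# Feature row of the first burst of a CENTRED burst tibble.
burst_features <- function(centred, window = 22L) {
  ft <- feature_matrix(centred, window = window)
  unlist(ft[1, feature_names()])
}

# Synthetic mean-ODBA cells with controllable covariates (for the smooth
# models without going through the record pipeline).
make_odba_cells <- function(n = 40, seed = 1, effect = function(bg) 0,
                            noise_sd = 1) {
  set.seed(seed)
  bg <- rep(seq(40, 59, length.out = 20), length.out = n)
  hour <- rep(12:17, length.out = n)
  tibble::tibble(
    blackglobe_bin = as.integer(round(bg)), hour = hour, month = 10L,
    individual_id = "i1", category = "grazing",
    mean_odba = 50 + effect(bg) + rnorm(n, 0, noise_sd),
    n_recordings = 30L
  )
}

# Null diel cells: identical hot/cool diel curves, binomial sampling.
make_null_diel_cells <- function(seed, n_ind = 4, n_per_cell = 120) {
  set.seed(seed)
  p_h <- 0.25 + 0.15 * cos(2 * pi * (0:23 - 6) / 24)
  grid <- expand.grid(hour = 0:23, individual_id = paste0("i", seq_len(n_ind)),
                      dayclass = c("cool", "hot"), stringsAsFactors = FALSE)
  k <- rbinom(nrow(grid), n_per_cell, p_h[grid$hour + 1])
  tibble::tibble(dayclass = grid$dayclass, hour = grid$hour,
                 individual_id = grid$individual_id, category = "grazing",
                 proportion = k / n_per_cell, n_records = n_per_cell)
}

# Run a small heat-response recovery simulation and return the
# temperature-smooth p-value and whether its partial effect decreases.
heat_sim <- function(seed, null = FALSE, n_individuals = 3, n_days = 30) {
  cfg <- if (null) {
    scenario_null(n_individuals = n_individuals, n_days = n_days, seed = seed)
  } else {
    scenario_config(n_individuals = n_individuals, n_days = n_days, seed = seed)
  }
  tl <- simulate_timeline(cfg)
  rec <- suppressMessages(consolidate_records(tl$ticks))
  rec <- suppressMessages(join_weather(rec, thermal_series(tl$weather)))
  rec <- add_time_fields(rec)
  cells <- time_budget(afternoon_filter(rec))
  fit <- suppressWarnings(fit_heat_model(cells, "grazing"))
  pe <- partial_effect(fit, "s(blackglobe)", n = 20)
  list(p = unname(fit$terms$p_value[fit$terms$term == "s(blackglobe)"]),
       decreasing = pe$effect[1] > pe$effect[nrow(pe)])
}

# Run a small diel simulation under a given scenario and return the
# interaction p, intercept-contrast p and 24-h percentage difference.
diel_sim <- function(seed, scenario = c("null", "compensation", "reduction"),
                     n_individuals = 4, n_days = 20) {
  scenario <- match.arg(scenario)
  cfg <- switch(scenario,
    null = scenario_null(n_individuals = n_individuals, n_days = n_days,
                         seed = seed),
    compensation = scenario_diel_compensation(
      amp = 0.12, n_individuals = n_individuals, n_days = n_days, seed = seed),
    reduction = scenario_diel_reduction(
      factor = 0.8, n_individuals = n_individuals, n_days = n_days,
      seed = seed))
  tl <- simulate_timeline(cfg)
  rec <- suppressMessages(consolidate_records(tl$ticks))
  rec <- suppressMessages(join_weather(rec, thermal_series(tl$weather)))
  rec <- add_time_fields(rec)
  ex <- select_extreme_days(daily_max(tl$weather), n = 10)
  fit <- suppressWarnings(fit_diel_model(diel_budget(rec, ex), "grazing"))
  list(interaction_p = fit$interaction_p, intercept_p = fit$intercept_p,
       pct = fit$pct_diff_24h)
}
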