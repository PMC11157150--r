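test_that("burst simulation is seed-deterministic and respects count bounds", {
  b1 <- simulate_burst("walking", seed = 9)
  b2 <- simulate_burst("walking", seed = 9)
  expect_identical(b1, b2)
  b3 <- simulate_burst("walking", seed = 10)
  expect_false(identical(b1$x, b3$x))
  expect_error(simulate_burst("flying"), "no signal model")

  tr <- simulate_training_set(n_per_class = 5, seed = 2)
  expect_silent(validate_bursts(tr))
  expect_identical(nrow(tr), 60L)
})

test_that("a noiseless still behaviour produces a constant burst at its posture", {
  models <- default_signal_models()
  models[["low-activity"]]$noise_sd <- 0
  b <- simulate_burst("low-activity", models, seed = 1)
  expect_identical(unique(b$x[[1]]), 2048L)
  expect_identical(unique(b$z[[1]]), 2048L + 512L)
})

test_that("gait frequency planted in a walking burst is recovered by the features", {
  for (seed in 1:5) {
    b <- simulate_burst("walking", seed = seed)
    fv <- burst_features(center_bursts(b))
    expect_lt(abs(fv[["x_freqmain"]] - 1.5), 33.3 / 110)  # within one bin
  }
})

test_that("behaviour classes are separable in the 19-feature space", {
  tr <- simulate_training_set(n_per_class = 20, seed = 42)
  ft <- feature_matrix(center_bursts(tr))
  X <- scale(as.matrix(ft[, feature_names()]))
  lab <- ft$behaviour
  D <- as.matrix(dist(X))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(D[i, lab == lab[i] & seq_along(lab) != i])
    b <- min(tapply(D[i, lab != lab[i]], lab[lab != lab[i]], mean))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("the timeline matches the burst schedule arithmetic", {
  cfg <- scenario_config(n_individuals = 2, n_days = 20, seed = 1)
  tl <- simulate_timeline(cfg)
  expect_identical(nrow(tl$ticks), 2L * 20L * 288L)  # 5-min ticks per day
  # 5-minute spacing within an individual
  one <- tl$ticks[tl$ticks$individual_id == "ind01", ]
  expect_true(all(diff(as.numeric(one$timestamp)) == 300))
  # ground truth carries the planted parameters and the day classes
  expect_named(tl$truth,
               c("temperature_slopes", "diel_modifier", "odba_means",
                 "reference_blackglobe", "hot_days", "cool_days",
                 "persistence"))
  expect_identical(length(tl$truth$hot_days), 10L)
  expect_identical(length(intersect(tl$truth$hot_days, tl$truth$cool_days)), 0L)
})

test_that("zero temperature slopes leave behaviour independent of day class", {
  rejections <- 0L
  for (seed in 1:20) {
    cfg <- scenario_null(n_individuals = 2, n_days = 6, persistence = 0,
                         seed = seed)
    tl <- simulate_timeline(cfg)
    tl$ticks$date <- as.Date(tl$ticks$timestamp, tz = "UTC")
    tl$ticks$hot <- tl$ticks$date %in% tl$truth$hot_days
    hour <- as.integer(format(tl$ticks$timestamp, "%H", tz = "UTC"))
    aft <- tl$ticks[hour >= 12 & hour < 18, ]
    p <- suppressWarnings(stats::chisq.test(table(aft$hot, aft$behaviour)))$p.value
    rejections <- rejections + (p < 0.05)
  }
  expect_lte(rejections, 4L)  # about the nominal 5% rate
})

test_that("a planted negative grazing slope suppresses hot-afternoon grazing", {
  hits <- 0L
  for (seed in 1:50) {
    cfg <- scenario_config(n_individuals = 2, n_days = 10, seed = seed)
    tl <- simulate_timeline(cfg)
    tl$ticks$date <- as.Date(tl$ticks$timestamp, tz = "UTC")
    hour <- as.integer(format(tl$ticks$timestamp, "%H", tz = "UTC"))
    aft <- tl$ticks[hour >= 12 & hour < 18, ]
    hot <- aft$date %in% tl$truth$hot_days
    p_hot <- mean(aft$behaviour[hot] == "grazing")
    p_cool <- mean(aft$behaviour[!hot] == "grazing")
    hits <- hits + (p_hot < p_cool)
  }
  expect_gte(hits, 48L)  # >= 95% of seeds
})

test_that("fixture suites are byte-identical under the same seed", {
  d1 <- tempfile("fix1"); d2 <- tempfile("fix2")
  cfg <- scenario_config(n_individuals = 1, n_days = 20, seed = 3)
  p1 <- make_fixture_suite(d1, seed = 3, n_per_class = 5, config = cfg)
  p2 <- make_fixture_suite(d2, seed = 3, n_per_class = 5, config = cfg)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  # the scenario spans enough distinct days for 10+10 extreme-day selection
  wx <- read_weather(p1[["weather"]])
  expect_gte(length(unique(as.Date(wx$timestamp, tz = "UTC"))), 20L)
  expect_true(file.exists(p1[["truth"]]))
})
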