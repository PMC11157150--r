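test_that("the blackglobe estimator is monotone and respects its config", {
  # identity fallback
  expect_message(bg <- blackglobe(30, 0, 50, coefficients = "identity"),
                 "identity fallback")
  expect_identical(bg, 30)
  # missing coefficients are named in the error
  expect_error(blackglobe(30, 500, 50, coefficients = list(intercept = 1)),
               "air_temp.*solar.*rh")
  # monotone in solar and air at fixed other inputs
  solar <- seq(0, 1000, by = 50)
  expect_true(all(diff(blackglobe(30, solar, 40)) >= 0))
  air <- seq(0, 45, by = 1)
  expect_true(all(diff(blackglobe(air, 500, 40)) > 0))
  # globe at or above air whenever the sun is up (default coefficients)
  grid <- expand.grid(air = seq(0, 45, by = 5), solar = c(50, 300, 900),
                      rh = c(5, 50, 100))
  expect_true(all(blackglobe(grid$air, grid$solar, grid$rh) >= grid$air))
  # vectorized equals scalar application
  vec <- blackglobe(grid$air, grid$solar, grid$rh)
  sca <- mapply(blackglobe, grid$air, grid$solar, grid$rh)
  expect_equal(vec, sca)
  expect_error(blackglobe(30, 100, 120), "\\[0, 100\\]")
})

test_that("daily maxima pick one value per calendar date", {
  ts <- as.POSIXct("2020-10-01 00:00:00", tz = "UTC") + (0:47) * 3600
  temp <- rep(20, 48)
  temp[15] <- 35   # day 1, 14:00
  temp[24 + 15] <- 31
  dm <- daily_max(tibble::tibble(timestamp = ts, air_temp = temp))
  expect_identical(nrow(dm), 2L)
  expect_equal(dm$max, c(35, 31))
  expect_identical(dm$date, as.Date(c("2020-10-01", "2020-10-02")))
  # one record per day reduces to the identity
  one <- tibble::tibble(timestamp = ts[seq(1, 48, by = 24)], air_temp = c(3, 9))
  expect_equal(daily_max(one)$max, c(3, 9))
})

test_that("extreme-day selection returns disjoint ordered top and bottom sets", {
  dates <- as.Date("2020-10-01") + 0:19
  dmax <- tibble::tibble(date = dates, max = c(21:40))
  ex <- select_extreme_days(dmax, n = 10)
  expect_identical(ex$hottest, dates[11:20])
  expect_identical(ex$coolest, dates[1:10])
  expect_identical(length(intersect(ex$hottest, ex$coolest)), 0L)
  # every hottest max >= every coolest max
  expect_gte(min(dmax$max[dmax$date %in% ex$hottest]),
             max(dmax$max[dmax$date %in% ex$coolest]))
  # hand-computed mean of the coolest maxima
  expect_equal(mean(dmax$max[dmax$date %in% ex$coolest]), mean(21:30))
  expect_error(select_extreme_days(dmax[1:19, ], n = 10), "at least 20")
})

test_that("ties and window months are handled deterministically", {
  dates <- as.Date("2020-09-28") + 0:24  # spans Sep into Oct
  dmax <- tibble::tibble(date = dates, max = rep(30, 25))
  dmax$max[dates >= as.Date("2020-10-01")] <- c(rep(30, 11), rep(40, 11))
  ex <- select_extreme_days(dmax, n = 10, months = c(10, 11, 12))
  # September dates never selected
  expect_true(all(format(c(ex$hottest, ex$coolest), "%m") != "09"))
  # ties resolved towards the earlier date
  oct <- dates[dates >= as.Date("2020-10-01")]
  expect_identical(ex$coolest, oct[1:10])
  expect_identical(ex$hottest, oct[12:21])
})
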