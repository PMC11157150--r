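mk_thermal <- function(hours = 0:23, date = "2020-10-01") {
  tibble::tibble(
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + hours * 3600,
    air_temp = 25, solar = 0, rh = 50, blackglobe = 30 + hours
  )
}

test_that("the weather join matches the nearest record within tolerance", {
  th <- mk_thermal()
  rec <- tibble::tibble(
    timestamp = as.POSIXct("2020-10-01 05:00:00", tz = "UTC") + c(0, 29, 31) * 60
  )
  rec$timestamp[3] <- as.POSIXct("2020-10-01 23:31:00", tz = "UTC")  # 31 min past last record
  out <- suppressMessages(join_weather(rec, th, tolerance_min = 30))
  expect_identical(nrow(out), 2L)
  expect_equal(out$blackglobe[1], 35)  # exact 05:00 match
  expect_equal(out$blackglobe[2], 35)  # 05:29 -> nearest 05:00
  expect_identical(attr(out, "n_unmatched"), 1L)
  expect_lte(nrow(out), nrow(rec))
  expect_error(join_weather(rec, th[0, ]), "empty")
})

test_that("the afternoon filter keeps 12:00-17:59 local", {
  rec <- tibble::tibble(
    timestamp = as.POSIXct("2020-10-01 00:00:00", tz = "UTC") + (0:23) * 3600
  )
  rec <- add_time_fields(rec)
  aft <- afternoon_filter(rec)
  expect_identical(aft$hour, 12:17)
  expect_equal(nrow(aft) / nrow(rec), 6 / 24)
  expect_identical(nrow(afternoon_filter(rec[0, ])), 0L)
  # boundary: 12:00 kept, 18:00 dropped
  expect_true(12L %in% aft$hour && !18L %in% aft$hour)
  # timezone offset moves the window coherently
  rec2 <- add_time_fields(rec, tz_offset_hours = 2)
  expect_identical(afternoon_filter(rec2)$hour, 12:17)
})

test_that("time budgets normalise to one within every cell", {
  rec <- tibble::tibble(
    individual_id = "i1",
    category = c(rep("grazing", 3), "resting"),
    blackglobe = 45.7, hour = 14L, month = 10L
  )
  tb <- time_budget(rec)
  expect_identical(unique(tb$blackglobe_bin), 45L)  # floor binning
  expect_equal(tb$proportion[tb$category == "grazing"], 0.75)
  expect_equal(tb$proportion[tb$category == "resting"], 0.25)
  expect_equal(sum(tb$proportion), 1)
  expect_identical(unique(tb$n_records), 4L)

  # order invariance and conservation on a larger random fixture
  set.seed(3)
  rec2 <- tibble::tibble(
    individual_id = sample(c("i1", "i2"), 500, TRUE),
    category = sample(analysis_categories(), 500, TRUE),
    blackglobe = runif(500, 40, 60),
    hour = sample(12:17, 500, TRUE), month = sample(10:12, 500, TRUE)
  )
  tb2 <- time_budget(rec2)
  shuffled <- time_budget(rec2[sample(nrow(rec2)), ])
  expect_equal(dplyr::arrange(tb2, blackglobe_bin, hour, month, individual_id,
                              category),
               dplyr::arrange(shuffled, blackglobe_bin, hour, month,
                              individual_id, category))
  sums <- tapply(tb2$proportion,
                 paste(tb2$blackglobe_bin, tb2$hour, tb2$month,
                       tb2$individual_id), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # total records across cells = input size (each cell counted once)
  cells <- unique(tb2[, c("blackglobe_bin", "hour", "month", "individual_id",
                          "n_records")])
  expect_identical(sum(cells$n_records), nrow(rec2))
})

test_that("mean-ODBA cells honour the 30-recording support rule", {
  rec <- tibble::tibble(
    individual_id = "i1", category = "grazing",
    blackglobe = 45, hour = 14L, month = 10L, odba = as.numeric(1:30)
  )
  out <- suppressMessages(mean_odba_cells(rec))
  expect_identical(nrow(out), 1L)
  expect_equal(out$mean_odba, 15.5)
  expect_identical(out$n_recordings, 30L)
  # 29 recordings: the cell disappears
  out29 <- suppressMessages(mean_odba_cells(rec[1:29, ]))
  expect_identical(nrow(out29), 0L)
  expect_identical(attr(out29, "n_discarded"), 1L)
})

test_that("diel budgets cover both day classes on extreme days only", {
  dates <- as.Date("2020-10-01") + 0:3
  ex <- structure(list(hottest = dates[1], coolest = dates[2],
                       criterion = "daily max air temperature"),
                  class = "extreme_days")
  rec <- tibble::tibble(
    individual_id = "i1",
    category = rep(c("grazing", "resting"), 8),
    date = rep(dates, each = 4),
    hour = rep(c(6L, 6L, 14L, 14L), 4)
  )
  db <- diel_budget(rec, ex)
  expect_identical(sort(unique(db$dayclass)), c("cool", "hot"))
  # non-extreme days contribute nothing: 2 days x 2 hours x 2 records
  cells <- unique(db[, c("dayclass", "hour", "individual_id", "n_records")])
  expect_identical(sum(cells$n_records), 8L)
  # hand check: each (dayclass, hour) cell is half grazing
  expect_true(all(db$proportion[db$category == "grazing"] == 0.5))
  expect_true(all(db$proportion[db$category == "walking"] == 0))
})
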