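test_that("removing the penalty recovers the unpenalized regression on the same basis", {
  cells <- make_odba_cells(n = 40, seed = 1,
                           effect = function(bg) -0.5 * (bg - 50))
  fit <- fit_heat_model(cells, "grazing", response = "mean_odba",
                        k_blackglobe = 4, k_hour = 4, sp = c(0, 0))
  gam <- fit$gam
  X <- predict(gam, type = "lpmatrix")
  lm_fit <- stats::lm.fit(X, cells$mean_odba)
  expect_equal(unname(fitted(gam)), unname(lm_fit$fitted.values),
               tolerance = 1e-6)
})

test_that("concurvity is near zero for independent covariates and near one for duplicates", {
  cells <- make_odba_cells(n = 120, seed = 2)
  # de-correlate hour and blackglobe by shuffling hour
  set.seed(3)
  cells$hour <- sample(cells$hour)
  fit <- fit_heat_model(cells, "grazing", response = "mean_odba",
                        k_blackglobe = 5, k_hour = 4)
  cv <- concurvity_values(fit)
  expect_true(all(cv >= 0 & cv <= 1))
  expect_lt(cv[["s(blackglobe)"]], 0.3)

  dup <- make_odba_cells(n = 120, seed = 4)
  dup$hour <- dup$blackglobe_bin / 3  # hour a deterministic function of temperature
  expect_warning(
    fit_dup <- fit_heat_model(dup, "grazing", response = "mean_odba",
                              k_blackglobe = 5, k_hour = 5),
    "concurvity"
  )
  expect_gt(max(concurvity_values(fit_dup)), 0.95)
})

test_that("partial effects of a null model stay flat within two standard errors", {
  # the unpenalized linear component of the smooth gives each seed a ~5%
  # chance of a spurious trend, so flatness is asserted across seeds
  flat <- vapply(1:20, function(seed) {
    cells <- make_odba_cells(n = 60, seed = seed)  # no planted effect
    fit <- fit_heat_model(cells, "grazing", response = "mean_odba")
    pe <- partial_effect(fit, "s(blackglobe)", n = 50)
    all(abs(pe$effect) <= 2 * pe$se)
  }, logical(1))
  expect_gte(sum(flat), 16L)
})

test_that("heat model enforces its preconditions and defaults", {
  cells <- make_odba_cells(n = 10, seed = 5)
  expect_error(fit_heat_model(cells, "grazing", response = "mean_odba"),
               "at least 20 cells")
  fit <- fit_heat_model(make_odba_cells(n = 40, seed = 6), "grazing",
                        response = "mean_odba")
  expect_identical(fit$alpha, 0.05)
  expect_true(all(fit$terms$p_value >= 0 & fit$terms$p_value <= 1,
                  na.rm = TRUE))
  expect_true(all(fit$terms$edf >= 0, na.rm = TRUE))
})

test_that("diel model demands both day classes and adequate hour coverage", {
  cells <- make_null_diel_cells(1)
  expect_error(fit_diel_model(cells[cells$dayclass == "hot", ], "grazing"),
               "both day classes")
  sparse <- cells[cells$hour < 8, ]
  expect_error(fit_diel_model(sparse, "grazing"), "12 distinct hours")
})

test_that("the intercept contrast p-value is near-uniform under the null", {
  pvals <- vapply(1:200, function(s) {
    suppressWarnings(fit_diel_model(make_null_diel_cells(s),
                                    "grazing"))$intercept_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))$statistic
  expect_lt(unname(ks), 0.15)
})
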