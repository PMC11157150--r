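test_that("time-domain features follow the population convention", {
  expect_equal(time_features(rep(7, 10)),
               c(mean = 7, variance = 0, sd = 0, max = 7, min = 7, range = 0))
  expect_equal(time_features(c(-1, 1)),
               c(mean = 0, variance = 1, sd = 1, max = 1, min = -1, range = 2))
  set.seed(41)
  v <- rnorm(50)
  tf <- time_features(v); tfn <- time_features(-v)
  expect_equal(tf[c("variance", "sd", "range")],
               tfn[c("variance", "sd", "range")])
  expect_error(time_features(3), "length >= 2")
})

test_that("spectral features locate a planted tone and match a brute-force DFT", {
  fs <- 33.3; n <- 110
  tt <- (0:(n - 1)) / fs
  tone <- 100 * sin(2 * pi * 2.0 * tt + 0.4)
  ff <- freq_features(tone, fs)
  expect_lt(abs(ff["freqmain"] - 2.0), fs / n)     # within one bin width
  # amplitude recovery is exact for an on-bin tone (no spectral leakage)
  on_bin <- 100 * sin(2 * pi * (7 * fs / n) * tt + 0.4)
  expect_equal(freq_features(on_bin, fs)["freqamp"], c(freqamp = 100),
               tolerance = 1e-6)
  # oracle agreement: bin of the max and entropy
  mags <- oracle_dft_mags(tone)
  expect_equal(unname(ff["freqmain"]), which.max(mags) * fs / n)
  expect_equal(unname(ff["entropy"]), oracle_entropy(tone), tolerance = 1e-9)
  expect_lte(ff["freqmain"], fs / 2)

  expect_equal(freq_features(rep(5, 16), fs),
               c(freqmain = 0, freqamp = 0, entropy = 0))

  two_tone <- tone + 100 * sin(2 * pi * 8 * tt)
  expect_gt(freq_features(two_tone, fs)["entropy"], ff["entropy"])
})

test_that("a flat spectrum resolves frequency ties to the lowest bin", {
  # an impulse has equal magnitude in every bin
  v <- c(8, rep(0, 7))
  ff <- freq_features(v, fs = 8)
  expect_equal(unname(ff["freqmain"]), 1 * 8 / 8)  # lowest non-DC bin
  expect_equal(unname(ff["entropy"]), 1)           # maximally unpredictable
})

test_that("ODBA matches the brute-force oracle and its edge cases", {
  expect_equal(odba(rep(3, 30), rep(-2, 30), rep(9, 30), window = 10), 0)
  # hand-computed closed form under the truncated-edge convention:
  # running means for x = (0,0,4,0,0), w = 5 are (4/3, 1, 4/5, 1, 4/3),
  # so ODBA = mean(4/3, 1, 16/5, 1, 4/3) = 118/75
  x <- c(0, 0, 4, 0, 0); y <- rep(1, 5); z <- rep(-2, 5)
  expect_equal(odba(x, y, z, window = 5), 118 / 75)
  set.seed(51)
  for (i in 1:10) {
    n <- sample(10:110, 1)
    w <- sample(1:n, 1)
    x <- rnorm(n, 0, 100); y <- rnorm(n, 0, 100); z <- rnorm(n, 0, 100)
    expect_equal(odba(x, y, z, w), oracle_odba(x, y, z, w), tolerance = 1e-9)
  }
  expect_error(odba(rnorm(10), rnorm(10), rnorm(10), window = 11), "1..n")
})

test_that("the feature vector has 19 features with the documented degeneracies", {
  expect_identical(length(feature_names()), 19L)
  cb <- center_bursts(make_burst(rep(2100, 110), rep(2000, 110), rep(2048, 110)))
  fv <- burst_features(cb)
  expect_identical(length(fv), 19L)
  expect_equal(unname(fv["x_mean"]), 52)
  expect_equal(unname(fv[c("x_variance", "x_sd", "x_range", "x_freqmain",
                           "x_freqamp", "x_entropy", "yz_variance", "odba")]),
               rep(0, 8))
})

test_that("yz features are invariant to collar rotation of the burst", {
  cb <- center_bursts(rand_raw_burst(seed = 61))
  fv0 <- burst_features(cb)
  set.seed(62)
  theta <- runif(1, 0, 2 * pi)
  r <- rotate_yz(as.numeric(cb$y[[1]]), as.numeric(cb$z[[1]]), theta)
  cb2 <- cb
  cb2$y <- list(r$y); cb2$z <- list(r$z)
  cb2$ayz <- list(sqrt(r$y^2 + r$z^2))
  fv1 <- burst_features(cb2)
  yz <- grep("^yz_", feature_names(), value = TRUE)
  expect_equal(fv0[yz], fv1[yz], tolerance = 1e-9)
})

test_that("features obey the scaling laws under count rescaling", {
  cb <- center_bursts(rand_raw_burst(seed = 71))
  fv <- burst_features(cb)
  k <- 3
  cbk <- cb
  cbk$x <- list(cb$x[[1]] * k); cbk$y <- list(cb$y[[1]] * k)
  cbk$z <- list(cb$z[[1]] * k); cbk$ayz <- list(cb$ayz[[1]] * k)
  fvk <- burst_features(cbk)
  linear <- c("x_mean", "x_sd", "x_max", "x_min", "x_range", "x_freqamp",
              "yz_mean", "yz_sd", "yz_max", "yz_min", "yz_range",
              "yz_freqamp", "odba")
  expect_equal(fvk[linear], k * fv[linear], tolerance = 1e-9)
  expect_equal(fvk[c("x_variance", "yz_variance")],
               k^2 * fv[c("x_variance", "yz_variance")], tolerance = 1e-9)
  invariant <- c("x_freqmain", "x_entropy", "yz_freqmain", "yz_entropy")
  expect_equal(fvk[invariant], fv[invariant], tolerance = 1e-9)
})

test_that("white noise carries more spectral entropy than a pure tone", {
  fs <- 33.3; n <- 110
  tt <- (0:(n - 1)) / fs
  set.seed(81)
  for (i in 1:100) {
    noise_ent <- freq_features(rnorm(n), fs)["entropy"]
    tone_ent <- freq_features(50 * sin(2 * pi * runif(1, 0.5, 10) * tt +
                                         runif(1, 0, 2 * pi)), fs)["entropy"]
    expect_gt(noise_ent, tone_ent)
  }
})
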