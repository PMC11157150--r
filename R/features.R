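## Per-burst feature extraction: time-domain and frequency-domain
## descriptors for the surge axis (x) and the yz-plane magnitude (ayz),
## plus tri-axial ODBA. 2 channels x 9 features + ODBA = 19 features.

#' Names of the 19 per-burst classification features
#'
#' @return Character vector of length 19 giving the stable column order of
#'   feature matrices.
#' @export
feature_names <- function() {
  per_channel <- c("mean", "variance", "sd", "max", "min", "range",
                   "freqmain", "freqamp", "entropy")
  c(paste0("x_", per_channel), paste0("yz_", per_channel), "odba")
}

#' Time-domain descriptors of a centred series
#'
#' Variance uses the population convention (divide by N), the usual choice
#' for descriptive burst features; `range = max - min`.
#'
#' @param series Numeric vector of length >= 2.
#' @return Named numeric vector `(mean, variance, sd, max, min, range)`.
#' @export
time_features <- function(series) {
  if (length(series) < 2L) abort("time_features needs a series of length >= 2")
  m <- mean(series)
  v <- mean((series - m)^2)
  c(mean = m, variance = v, sd = sqrt(v),
    max = max(series), min = min(series), range = max(series) - min(series))
}

#' Frequency-domain descriptors of a centred series
#'
#' The discrete Fourier magnitude spectrum of the mean-removed series is
#' taken over bins `1..floor(N/2)`; the DC bin is excluded so posture does
#' not leak into the spectral features. `freqmain` is the frequency of the
#' largest magnitude (ties broken towards the lowest frequency),
#' `freqamp` is that magnitude scaled by `2/N` so a pure sine of amplitude
#' A reports approximately A, and `entropy` is the Shannon entropy of the
#' magnitude-normalised spectrum divided by `log(nbins)` so it lies in
#' \[0, 1\]. A spectrum with no dynamic content returns `(0, 0, 0)`.
#'
#' @param series Numeric vector of length >= 4.
#' @param fs Sampling frequency in Hz.
#' @return Named numeric vector `(freqmain, freqamp, entropy)`.
#' @export
freq_features <- function(series, fs) {
  n <- length(series)
  if (n < 4L) abort("freq_features needs a series of length >= 4")
  if (!is.finite(fs) || fs <= 0) abort("fs must be > 0")
  mags <- Mod(fft(series - mean(series)))[2:(n %/% 2 + 1L)]
  total <- sum(mags)
  if (total <= .Machine$double.eps * n) {
    return(c(freqmain = 0, freqamp = 0, entropy = 0))
  }
  k <- which.max(mags)  # which.max takes the first maximum: lowest frequency
  p <- mags / total
  p <- p[p > 0]
  ent <- if (length(mags) > 1L) -sum(p * log(p)) / log(length(mags)) else 0
  c(freqmain = k * fs / n, freqamp = 2 * mags[k] / n, entropy = ent)
}

## Centred running mean with truncated (shrinking) windows at the edges.
## For window w the nominal span at index i is i-floor((w-1)/2) ..
## i+ceiling((w-1)/2), clamped to 1..n.
running_mean <- function(v, window) {
  n <- length(v)
  lo <- pmax(seq_len(n) - (window - 1L) %/% 2L, 1L)
  hi <- pmin(seq_len(n) + window %/% 2L, n)
  cs <- c(0, cumsum(v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Overall dynamic body acceleration of one burst
#'
#' The static component of each axis is estimated as a centred running
#' mean over `window` samples (windows shrink at the burst edges rather
#' than padding); the dynamic component is the residual. ODBA is the mean
#' over samples of the sum of absolute dynamic components of all three
#' axes — the standard energy-expenditure proxy, here in counts.
#'
#' @param x,y,z Centred numeric vectors of equal length.
#' @param window Running-window length in samples; default 22, one fifth
#'   of a 110-sample burst (0.67 s at 33.3 Hz). Must satisfy
#'   `1 <= window <= length(x)`.
#' @return ODBA in counts (non-negative scalar).
#' @export
odba <- function(x, y, z, window = 22L) {
  n <- length(x)
  if (length(y) != n || length(z) != n) abort("axes must have equal length")
  if (window < 1L || window > n) abort("window must lie in 1..n")
  dyn <- function(v) v - running_mean(v, window)
  mean(abs(dyn(x)) + abs(dyn(y)) + abs(dyn(z)))
}

#' Feature vector of a single centred burst
#'
#' @param x,y,z,ayz Centred axis series and yz-plane magnitude of one
#'   burst.
#' @param fs Sampling frequency in Hz.
#' @param window ODBA running-window length in samples.
#' @return Named numeric vector of the 19 features in [feature_names()]
#'   order.
#' @export
feature_vector <- function(x, y, z, ayz, fs, window = 22L) {
  fx <- c(time_features(x), freq_features(x, fs))
  fyz <- c(time_features(ayz), freq_features(ayz, fs))
  out <- c(setNames(fx, paste0("x_", names(fx))),
           setNames(fyz, paste0("yz_", names(fyz))),
           odba = odba(x, y, z, window))
  out[feature_names()]
}

#' Feature matrix of a burst set
#'
#' Applies [feature_vector()] to every row of a centred burst tibble.
#'
#' @param bursts A centred burst tibble (see [center_bursts()]).
#' @param window ODBA running-window length in samples (default 22).
#' @return A tibble with `individual_id`, `timestamp` (and `behaviour`
#'   when present) followed by the 19 feature columns in stable order.
#' @export
feature_matrix <- function(bursts, window = 22L) {
  if (!"ayz" %in% names(bursts)) {
    abort("bursts must be centred first (no `ayz` column); see center_bursts()")
  }
  feats <- t(mapply(feature_vector, bursts$x, bursts$y, bursts$z, bursts$ayz,
                    bursts$fs, MoreArgs = list(window = window)))
  out <- tibble::tibble(individual_id = bursts$individual_id,
                        timestamp = bursts$timestamp)
  if ("behaviour" %in% names(bursts)) out$behaviour <- bursts$behaviour
  dplyr::bind_cols(out, tibble::as_tibble(feats))
}

#' Write a feature matrix as delimited text
#'
#' Columns are written in the documented stable order ([feature_names()]).
#'
#' @param features A feature tibble from [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
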