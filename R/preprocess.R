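## Centring, unit conversion and collar-orientation harmonisation.

#' Centre raw counts and derive the yz-plane magnitude
#'
#' Raw 12-bit counts are centred by subtracting 2048 (the zero-acceleration
#' level), and the per-sample yz-plane magnitude
#' `ayz[i] = sqrt(y[i]^2 + z[i]^2)` is added. `ayz` is invariant to collar
#' rotation about the neck axis, which rotates the (y, z) pair.
#'
#' @param bursts A burst tibble of raw counts (see [read_bursts()]).
#' @return The same tibble with `x`, `y`, `z` replaced by centred (signed)
#'   values and a new list-column `ayz`.
#' @export
center_bursts <- function(bursts) {
  validate_bursts(bursts)
  bursts$x <- lapply(bursts$x, function(v) v - 2048L)
  bursts$y <- lapply(bursts$y, function(v) v - 2048L)
  bursts$z <- lapply(bursts$z, function(v) v - 2048L)
  bursts$ayz <- mapply(function(y, z) sqrt(as.numeric(y)^2 + as.numeric(z)^2),
                       bursts$y, bursts$z, SIMPLIFY = FALSE)
  bursts
}

#' Convert centred counts to units of G
#'
#' The sensor maps raw counts 0..4095 linearly onto -4 G..+4 G, so a
#' centred count converts with slope 8/4096 G per count and zero maps to
#' zero. Features are computed on counts; this conversion is provided for
#' reporting.
#'
#' @param centered Numeric vector of centred counts.
#' @return Acceleration in G.
#' @export
#' @examples
#' counts_to_g(c(0, 1024, 2047))
counts_to_g <- function(centered) {
  centered * (8 / 4096)
}

#' Decide whether x/y axis orientation must be reversed
#'
#' Collar fitment can leave the surge (x) and sway (y) axes pointing the
#' opposite way on a deployment relative to the animals the classifier was
#' trained on. The per-axis mean over all samples of the training set is
#' compared with the mean over the inference set for one individual; an
#' axis is flagged for flipping when the two means have opposite signs and
#' both magnitudes exceed a noise floor (so near-zero means never trigger
#' a flip). Only x and y are ever flipped, never heave (z).
#'
#' @param train_bursts,infer_bursts Centred burst tibbles (see
#'   [center_bursts()]); both must be non-empty.
#' @param floor Magnitude floor in centred counts (default 100, about
#'   0.2 G) below which a mean is treated as uninformative.
#' @return A list of class `"orientation_decision"` with elements
#'   `individual_id`, `flip_x`, `flip_y` and the four means.
#' @export
decide_orientation <- function(train_bursts, infer_bursts, floor = 100) {
  if (nrow(train_bursts) == 0L || nrow(infer_bursts) == 0L) {
    abort("both training and inference burst sets must be non-empty")
  }
  mean_axis <- function(bursts, axis) mean(unlist(bursts[[axis]]))
  tm_x <- mean_axis(train_bursts, "x"); tm_y <- mean_axis(train_bursts, "y")
  im_x <- mean_axis(infer_bursts, "x"); im_y <- mean_axis(infer_bursts, "y")
  flip <- function(tm, im) {
    sign(tm) != sign(im) && abs(tm) > floor && abs(im) > floor
  }
  structure(
    list(
      individual_id = unique(infer_bursts$individual_id),
      flip_x = flip(tm_x, im_x), flip_y = flip(tm_y, im_y),
      train_mean_x = tm_x, train_mean_y = tm_y,
      infer_mean_x = im_x, infer_mean_y = im_y,
      floor = floor
    ),
    class = "orientation_decision"
  )
}

#' @export
print.orientation_decision <- function(x, ...) {
  cat("Orientation decision for",
      paste(x$individual_id, collapse = ", "), "\n")
  cat(sprintf("  x: train mean %.1f, infer mean %.1f -> flip_x = %s\n",
              x$train_mean_x, x$infer_mean_x, x$flip_x))
  cat(sprintf("  y: train mean %.1f, infer mean %.1f -> flip_y = %s\n",
              x$train_mean_y, x$infer_mean_y, x$flip_y))
  invisible(x)
}

#' Apply an orientation decision to centred bursts
#'
#' Negates the flagged axes elementwise and recomputes `ayz`. Applying the
#' same decision twice restores the original bursts.
#'
#' @param decision An `"orientation_decision"` from [decide_orientation()].
#' @param bursts A centred burst tibble.
#' @return The reoriented burst tibble.
#' @export
apply_orientation <- function(decision, bursts) {
  stopifnot(inherits(decision, "orientation_decision"))
  if (decision$flip_x) bursts$x <- lapply(bursts$x, function(v) -v)
  if (decision$flip_y) bursts$y <- lapply(bursts$y, function(v) -v)
  if ("ayz" %in% names(bursts)) {
    bursts$ayz <- mapply(function(y, z) sqrt(as.numeric(y)^2 + as.numeric(z)^2),
                         bursts$y, bursts$z, SIMPLIFY = FALSE)
  }
  bursts
}

#' Serialize orientation decisions to an audit table
#'
#' @param decisions A list of `"orientation_decision"` objects.
#' @param path Output path for a comma-separated audit file.
#' @return `path`, invisibly.
#' @export
write_orientation_audit <- function(decisions, path) {
  rows <- lapply(decisions, function(d) {
    tibble::tibble(
      individual_id = paste(d$individual_id, collapse = ";"),
      flip_x = d$flip_x, flip_y = d$flip_y,
      train_mean_x = d$train_mean_x, train_mean_y = d$train_mean_y,
      infer_mean_x = d$infer_mean_x, infer_mean_y = d$infer_mean_y
    )
  })
  write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}
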