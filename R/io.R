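## Reading and writing collar bursts, labels and weather series.
##
## A burst set is a tibble with one row per burst and columns
##   individual_id (chr), timestamp (POSIXct, UTC), fs (dbl), n (int),
##   x, y, z (list columns of integer raw counts, each of length n)
## plus, optionally, a `behaviour` column when labels travel with the bursts.
## Raw counts are 12-bit (0..4095); 2048 corresponds to zero acceleration.

MAX_COUNT <- 4095L

#' Describe the on-disk layout of a burst file
#'
#' Two dialects are supported and must be declared, never sniffed: the
#' Movebank-style `"interleaved"` layout where one column holds the
#' whitespace-separated sequence `x1 y1 z1 x2 y2 z2 ...`, and the
#' `"per_axis"` layout with three columns each holding one axis as a
#' whitespace-separated string.
#'
#' @param format `"interleaved"` or `"per_axis"`.
#' @param col_id,col_time,col_fs Names of the id, timestamp and sampling
#'   frequency columns.
#' @param col_acc Name of the interleaved acceleration column
#'   (interleaved dialect only).
#' @param col_x,col_y,col_z Per-axis column names (per_axis dialect only).
#' @param col_behaviour Optional name of a behaviour-label column; when
#'   present the labels are carried into the burst set.
#' @param time_format `strptime` format for timestamps; all timestamps are
#'   interpreted as UTC.
#'
#' @return A list of class `"burst_dialect"`.
#' @export
burst_dialect <- function(format = c("interleaved", "per_axis"),
                          col_id = "individual_id",
                          col_time = "timestamp",
                          col_fs = "fs",
                          col_acc = "acc",
                          col_x = "x", col_y = "y", col_z = "z",
                          col_behaviour = NULL,
                          time_format = "%Y-%m-%d %H:%M:%S") {
  format <- match.arg(format)
  structure(
    list(format = format, col_id = col_id, col_time = col_time,
         col_fs = col_fs, col_acc = col_acc,
         col_x = col_x, col_y = col_y, col_z = col_z,
         col_behaviour = col_behaviour, time_format = time_format),
    class = "burst_dialect"
  )
}

parse_count_string <- function(s) {
  as.integer(strsplit(trimws(s), "\\s+")[[1]])
}

burst_row_error <- function(row, reason) {
  tibble::tibble(row = as.integer(row), reason = reason)
}

#' Read collar accelerometer bursts from delimited text
#'
#' Each row of the file becomes one burst. Rows that fail validation
#' (counts outside 0..4095, unequal axis lengths, non-positive sampling
#' frequency, unparseable fields) are dropped and reported with their row
#' numbers in the `"errors"` attribute of the result, with a warning.
#'
#' @param path Path to a delimited text file (comma-separated).
#' @param dialect A [burst_dialect()] describing the column layout.
#'
#' @return A burst tibble (columns `individual_id`, `timestamp`, `fs`,
#'   `n`, `x`, `y`, `z`, and `behaviour` when the dialect declares a label
#'   column), with attribute `"errors"`: a tibble of `(row, reason)` for
#'   rejected rows.
#' @export
read_bursts <- function(path, dialect = burst_dialect()) {
  stopifnot(inherits(dialect, "burst_dialect"))
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    out <- empty_bursts(labelled = !is.null(dialect$col_behaviour))
    attr(out, "errors") <- burst_row_error(integer(), character())
    return(out)
  }
  need <- c(dialect$col_id, dialect$col_time, dialect$col_fs,
            if (dialect$format == "interleaved") dialect$col_acc
            else c(dialect$col_x, dialect$col_y, dialect$col_z),
            dialect$col_behaviour)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("burst file is missing declared columns: ",
                 paste(missing_cols, collapse = ", ")))
  }

  errors <- list()
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    parsed <- tryCatch(
      parse_burst_row(raw[i, , drop = FALSE], dialect),
      error = function(e) conditionMessage(e)
    )
    if (is.character(parsed)) {
      errors[[length(errors) + 1L]] <- burst_row_error(i, parsed)
    } else {
      rows[[i]] <- parsed
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0L) {
    empty_bursts(labelled = !is.null(dialect$col_behaviour))
  } else {
    dplyr::bind_rows(rows)
  }
  err <- if (length(errors) > 0L) dplyr::bind_rows(errors) else
    burst_row_error(integer(), character())
  if (nrow(err) > 0L) {
    warn(paste0(nrow(err), " burst row(s) failed validation and were dropped"))
  }
  attr(out, "errors") <- err
  out
}

parse_burst_row <- function(row, dialect) {
  fs <- as.numeric(row[[dialect$col_fs]])
  if (is.na(fs) || fs <= 0) stop("sampling frequency must be > 0")
  ts <- as.POSIXct(as.character(row[[dialect$col_time]]),
                   format = dialect$time_format, tz = "UTC")
  if (is.na(ts)) stop("unparseable timestamp")
  if (dialect$format == "interleaved") {
    v <- parse_count_string(as.character(row[[dialect$col_acc]]))
    if (anyNA(v)) stop("non-integer acceleration value")
    if (length(v) %% 3L != 0L) stop("interleaved count not divisible by 3")
    idx <- seq_len(length(v) / 3L)
    x <- v[3L * idx - 2L]; y <- v[3L * idx - 1L]; z <- v[3L * idx]
  } else {
    x <- parse_count_string(as.character(row[[dialect$col_x]]))
    y <- parse_count_string(as.character(row[[dialect$col_y]]))
    z <- parse_count_string(as.character(row[[dialect$col_z]]))
    if (anyNA(x) || anyNA(y) || anyNA(z)) stop("non-integer acceleration value")
    if (length(x) != length(y) || length(y) != length(z)) {
      stop("axis lengths differ")
    }
  }
  if (any(x < 0L | x > MAX_COUNT) || any(y < 0L | y > MAX_COUNT) ||
      any(z < 0L | z > MAX_COUNT)) {
    stop("count outside 0..4095")
  }
  out <- tibble::tibble(
    individual_id = as.character(row[[dialect$col_id]]),
    timestamp = ts, fs = fs, n = length(x),
    x = list(x), y = list(y), z = list(z)
  )
  if (!is.null(dialect$col_behaviour)) {
    out$behaviour <- as.character(row[[dialect$col_behaviour]])
  }
  out
}

empty_bursts <- function(labelled = FALSE) {
  out <- tibble::tibble(
    individual_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    fs = numeric(), n = integer(), x = list(), y = list(), z = list()
  )
  if (labelled) out$behaviour <- character()
  out
}

#' Write a burst set back to delimited text
#'
#' Inverse of [read_bursts()]: the written file read back under the same
#' dialect reproduces ids, timestamps and counts exactly.
#'
#' @param bursts A burst tibble.
#' @param path Output file path.
#' @param dialect A [burst_dialect()].
#' @return `path`, invisibly.
#' @export
write_bursts <- function(bursts, path, dialect = burst_dialect()) {
  collapse <- function(v) paste(v, collapse = " ")
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = bursts$individual_id,
    b = format(bursts$timestamp, dialect$time_format, tz = "UTC"),
    c = format(bursts$fs, trim = TRUE)
  )
  names(out) <- c(dialect$col_id, dialect$col_time, dialect$col_fs)
  if (dialect$format == "interleaved") {
    inter <- mapply(function(x, y, z) collapse(as.vector(rbind(x, y, z))),
                    bursts$x, bursts$y, bursts$z)
    out[[dialect$col_acc]] <- as.character(inter)
  } else {
    out[[dialect$col_x]] <- vapply(bursts$x, collapse, character(1))
    out[[dialect$col_y]] <- vapply(bursts$y, collapse, character(1))
    out[[dialect$col_z]] <- vapply(bursts$z, collapse, character(1))
  }
  if (!is.null(dialect$col_behaviour) && "behaviour" %in% names(bursts)) {
    out[[dialect$col_behaviour]] <- bursts$behaviour
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate structural invariants of a burst set
#'
#' Checks that all three axes have equal length `n`, every count lies in
#' 0..4095 and `fs > 0`. Called internally by readers; exported so
#' downstream code can assert the contract on bursts from any source.
#'
#' @param bursts A burst tibble.
#' @return `bursts`, invisibly; aborts on violation.
#' @export
validate_bursts <- function(bursts) {
  req <- c("individual_id", "timestamp", "fs", "n", "x", "y", "z")
  missing_cols <- setdiff(req, names(bursts))
  if (length(missing_cols) > 0L) {
    abort(paste0("burst set lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  for (i in seq_len(nrow(bursts))) {
    n <- bursts$n[[i]]
    lens <- c(length(bursts$x[[i]]), length(bursts$y[[i]]), length(bursts$z[[i]]))
    if (!all(lens == n)) abort(sprintf("burst %d: axis lengths %s != n = %d",
                                       i, paste(lens, collapse = "/"), n))
    counts <- c(bursts$x[[i]], bursts$y[[i]], bursts$z[[i]])
    if (any(counts < 0 | counts > MAX_COUNT)) {
      abort(sprintf("burst %d: count outside 0..%d", i, MAX_COUNT))
    }
    if (!is.finite(bursts$fs[[i]]) || bursts$fs[[i]] <= 0) {
      abort(sprintf("burst %d: fs must be > 0", i))
    }
  }
  invisible(bursts)
}

#' Read a weather-station series
#'
#' Expects columns `timestamp`, `air_temp` (deg C), `solar` (W/m2) and
#' `rh` (percent, 0..100). Timestamps must be strictly increasing and
#' relative humidity within 0..100; violations abort.
#'
#' @param path Path to a comma-separated file.
#' @param time_format `strptime` format, interpreted as UTC.
#' @return A tibble ordered in time with columns `timestamp`, `air_temp`,
#'   `solar`, `rh`.
#' @export
read_weather <- function(path, time_format = "%Y-%m-%d %H:%M:%S") {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "air_temp", "solar", "rh")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("weather file is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    timestamp = as.POSIXct(raw$timestamp, format = time_format, tz = "UTC"),
    air_temp = as.numeric(raw$air_temp),
    solar = as.numeric(raw$solar),
    rh = as.numeric(raw$rh)
  )
  if (nrow(out) == 0L) return(out)
  if (anyNA(out$timestamp)) abort("weather file has unparseable timestamps")
  if (any(diff(as.numeric(out$timestamp)) <= 0)) {
    abort("weather timestamps must be strictly increasing")
  }
  if (any(!is.finite(out$rh)) || any(out$rh < 0 | out$rh > 100)) {
    abort("relative humidity must lie in [0, 100]")
  }
  out
}

#' Split long recordings into equal sub-bursts
#'
#' Collars deployed for behaviour labelling record 6.6 s bursts that are
#' split into two 3.3 s halves before feature extraction; this generalises
#' to any integer number of parts. Timestamps of later parts are offset by
#' `(n/parts)/fs` seconds each.
#'
#' @param bursts A burst tibble.
#' @param parts Integer number of equal parts; every burst's `n` must be
#'   divisible by it.
#' @return A burst tibble with `parts` times as many rows.
#' @export
split_long_bursts <- function(bursts, parts = 2L) {
  parts <- as.integer(parts)
  if (parts < 1L) abort("parts must be >= 1")
  if (parts == 1L) return(bursts)
  if (any(bursts$n %% parts != 0L)) {
    abort("every burst length must be divisible by `parts`")
  }
  pieces <- lapply(seq_len(nrow(bursts)), function(i) {
    n_sub <- bursts$n[[i]] %/% parts
    fs <- bursts$fs[[i]]
    lapply(seq_len(parts), function(p) {
      idx <- ((p - 1L) * n_sub + 1L):(p * n_sub)
      row <- bursts[i, ]
      row$timestamp <- row$timestamp + (p - 1L) * n_sub / fs
      row$n <- n_sub
      row$x <- list(bursts$x[[i]][idx])
      row$y <- list(bursts$y[[i]][idx])
      row$z <- list(bursts$z[[i]][idx])
      row
    })
  })
  dplyr::bind_rows(unlist(pieces, recursive = FALSE))
}
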