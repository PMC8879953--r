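# Raw six-column sensor logs -> normalized one-second windows shaped for the
# posture classifier. Logs are nominally 50 Hz; windows are tumbling (stride =
# window length) so Level-1 events have a 1 Hz cadence.

axis_cols <- c("ax", "ay", "az")

#' Read and write six-column sensor logs
#'
#' The log format is CSV with columns, in order: sensor ID, frame number,
#' timestamp (s), and the three accelerometer axes x, y, z (arbitrary device
#' units). A header line is optional; column order is fixed.
#'
#' @param path File path.
#' @return A tibble with columns `sensor_id`, `frame_number`, `timestamp`,
#'   `ax`, `ay`, `az`.
#' @export
read_sensor_log <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("sensor", tolower(first))
  cols <- c("sensor_id", "frame_number", "timestamp", axis_cols)
  raw <- read.csv(path, header = has_header,
                  col.names = cols, stringsAsFactors = FALSE)
  tibble(sensor_id = as.character(raw$sensor_id),
         frame_number = as.integer(raw$frame_number),
         timestamp = as.numeric(raw$timestamp),
         ax = as.numeric(raw$ax), ay = as.numeric(raw$ay),
         az = as.numeric(raw$az))
}

#' @rdname read_sensor_log
#' @param samples A sample tibble as returned by [read_sensor_log()] or
#'   [generate_posture_signal()].
#' @export
write_sensor_log <- function(samples, path) {
  write.csv(as.data.frame(samples), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment a sensor log into tumbling one-second windows
#'
#' Cuts a single-sensor sample stream into consecutive, non-overlapping
#' windows of `rate_hz * window_s` samples (50 by default). A trailing
#' partial window is dropped. Samples must be sorted by strictly increasing
#' frame number, and the frame count must agree with the spanned time at the
#' nominal rate to within 5% (no resampling is attempted).
#'
#' @param samples Single-sensor sample tibble (see [read_sensor_log()]).
#' @param window_s Window length in seconds.
#' @param rate_hz Nominal sampling rate.
#' @return A tibble with one row per window: `sensor_id`, `start_t` (timestamp
#'   of the window's first sample) and `values`, a list column of
#'   `(rate_hz * window_s) x 3` matrices with columns x, y, z.
#' @examples
#' sig <- generate_posture_signal("Walk", seconds = 3, seed = 1)
#' segment_windows(sig)
#' @export
segment_windows <- function(samples, window_s = 1, rate_hz = 50) {
  stopifnot(window_s > 0, rate_hz > 0)
  n <- nrow(samples)
  empty <- tibble(sensor_id = character(), start_t = numeric(),
                  values = list())
  if (n == 0) return(empty)
  if (length(unique(samples$sensor_id)) > 1) {
    abort("segment_windows() expects samples from a single sensor")
  }
  if (is.unsorted(samples$frame_number, strictly = TRUE)) {
    abort("samples must be sorted by strictly increasing frame_number")
  }
  span <- samples$timestamp[n] - samples$timestamp[1]
  if (n > 1 && span > 0) {
    implied <- (n - 1) / span
    if (abs(implied - rate_hz) / rate_hz > 0.05) {
      abort(sprintf(paste0("sample count and time span disagree: implied rate ",
                           "%.1f Hz vs nominal %d Hz"), implied, rate_hz))
    }
  }
  per <- as.integer(round(rate_hz * window_s))
  k <- n %/% per
  if (k == 0) return(empty)
  mat <- as.matrix(samples[, axis_cols])
  idx0 <- (seq_len(k) - 1) * per
  tibble(
    sensor_id = samples$sensor_id[1],
    start_t = samples$timestamp[idx0 + 1],
    values = purrr::map(idx0, function(i) {
      m <- mat[(i + 1):(i + per), , drop = FALSE]
      dimnames(m) <- NULL
      m
    })
  )
}

#' Fit per-axis min-max normalization statistics
#'
#' Computes the per-sensor, per-axis minimum and maximum over a full
#' recording (or a calibration span of one). Because accelerometer ranges
#' differ between dogs and mounts, windows are later rescaled to \[0, 1\]
#' with these statistics before classification.
#'
#' @param samples Sample tibble, one or both sensors.
#' @return A tibble with columns `sensor_id`, `axis`, `min`, `max`.
#' @export
fit_stats <- function(samples) {
  if (nrow(samples) == 0) abort("cannot fit normalization stats on no samples")
  samples |>
    tidyr::pivot_longer(dplyr::all_of(axis_cols),
                        names_to = "axis", values_to = "v") |>
    dplyr::group_by(.data$sensor_id, .data$axis) |>
    dplyr::summarise(min = min(.data$v), max = max(.data$v), .groups = "drop")
}

#' Min-max normalize segmented windows
#'
#' Applies `(v - min) / (max - min)` per axis with the supplied statistics.
#' Values outside the calibration range are clipped to \[0, 1\]; a degenerate
#' axis (`max == min`) maps to 0.5 everywhere.
#'
#' @param windows A window tibble from [segment_windows()].
#' @param stats A statistics tibble from [fit_stats()] covering the windows'
#'   sensor.
#' @return `windows` with the `values` matrices rescaled to \[0, 1\] and an
#'   added logical column `normalized`.
#' @export
normalize_windows <- function(windows, stats) {
  if (nrow(windows) == 0) {
    return(dplyr::mutate(windows, normalized = logical(0)))
  }
  sensors <- unique(windows$sensor_id)
  missing <- setdiff(sensors, unique(stats$sensor_id))
  if (length(missing)) {
    abort(paste0("no normalization stats for sensor: ",
                 paste(missing, collapse = ", ")))
  }
  lookup <- split(stats, stats$sensor_id)
  out <- windows
  out$values <- purrr::map2(windows$values, windows$sensor_id, function(m, sid) {
    if (!is.matrix(m) || ncol(m) != 3) {
      abort("window values must be a timesteps x 3 matrix")
    }
    st <- lookup[[sid]]
    st <- st[match(axis_cols, st$axis), ]
    lo <- st$min
    hi <- st$max
    norm <- m
    for (j in 1:3) {
      if (hi[j] > lo[j]) {
        norm[, j] <- pmin(1, pmax(0, (m[, j] - lo[j]) / (hi[j] - lo[j])))
      } else {
        norm[, j] <- 0.5
      }
    }
    norm
  })
  dplyr::mutate(out, normalized = TRUE)
}

#' Stack normalized windows into a classifier input tensor
#'
#' @param windows A normalized window tibble ([normalize_windows()]).
#' @return A numeric array of shape `(samples, timesteps, 3)`, preserving
#'   window order; `0 x 50 x 3` for an empty input.
#' @export
to_tensor <- function(windows) {
  n <- nrow(windows)
  if (n == 0) return(array(numeric(0), dim = c(0, 50, 3)))
  dims <- purrr::map(windows$values, dim)
  first <- dims[[1]]
  if (is.null(first) || length(first) != 2 || first[2] != 3) {
    abort("window values must be timesteps x 3 matrices")
  }
  if (!all(purrr::map_lgl(dims, ~ identical(.x, first)))) {
    abort("ragged window batch: all windows must share the same shape")
  }
  out <- array(0, dim = c(n, first[1], 3))
  for (i in seq_len(n)) out[i, , ] <- windows$values[[i]]
  out
}
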