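#' Read a raw smartphone IMU log
#'
#' Parses the plain-text log dialect written by the capture app and by
#' [write_imu_log()]: one record per line with seven whitespace- or
#' comma-separated columns `t_ns ax ay az gx gy gz`, where `t_ns` is an
#' integer nanosecond timestamp, acceleration is in m/s^2 and angular
#' velocity in deg/s. Lines starting with `#` are comments and are skipped.
#'
#' Timestamps are converted to seconds from the first sample. Channel values
#' are range-checked against the sensor limits (+/-4 g for acceleration,
#' +/-500 deg/s for angular velocity); out-of-range values are clipped with
#' a warning reporting how many samples were affected.
#'
#' @param path path to a TXT log file.
#' @param axes axis labels of the file's channels (default device axes).
#' @return An [imu_recording()] with raw (non-uniform) timestamps
#'   (`rate = NA`).
#' @export
read_imu_log <- function(path, axes = c("x", "y", "z")) {
  if (!file.exists(path))
    stop_itug("itug_io_error", "log file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    stop_itug("itug_parse_error", "no data records in %s", path)
  parts <- strsplit(trimws(lines), "[[:space:],]+")
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop_itug("itug_parse_error",
              "malformed record on line %d of %s (expected 7 fields, got %d)",
              lineno[bad[1]], path, lengths(parts)[bad[1]])
  vals <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                 ncol = 7, byrow = TRUE)
  nab <- which(rowSums(is.na(vals)) > 0)
  if (length(nab))
    stop_itug("itug_parse_error", "non-numeric field on line %d of %s",
              lineno[nab[1]], path)
  t_ns <- vals[, 1]
  if (any(diff(t_ns) <= 0))
    stop_itug("itug_integrity_error",
              "non-monotone timestamp on line %d of %s",
              lineno[which(diff(t_ns) <= 0)[1] + 1L], path)
  acc <- vals[, 2:4, drop = FALSE]
  gyro <- vals[, 5:7, drop = FALSE]
  acc_lim <- 4 * 9.80665
  n_clip_a <- sum(abs(acc) > acc_lim)
  n_clip_g <- sum(abs(gyro) > 500)
  if (n_clip_a + n_clip_g > 0) {
    warning(sprintf(
      "%s: clipped %d acceleration and %d gyro samples to sensor range",
      path, n_clip_a, n_clip_g), call. = FALSE)
    acc <- pmin(pmax(acc, -acc_lim), acc_lim)
    gyro <- pmin(pmax(gyro, -500), 500)
  }
  imu_recording((t_ns - t_ns[1]) / 1e9, acc, gyro, rate = NA_real_,
                axes = axes)
}

#' Write an IMU recording as a plain-text log
#'
#' Emits the dialect read by [read_imu_log()]. Timestamps are written as
#' integer nanoseconds.
#'
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @param t0_ns nanosecond timestamp of the first sample (defaults to 0;
#'   real device clocks start at an arbitrary epoch).
#' @return `path`, invisibly.
#' @export
write_imu_log <- function(rec, path, t0_ns = 0) {
  t_ns <- round(rec$time * 1e9) + t0_ns
  body <- sprintf("%.0f %.6f %.6f %.6f %.6f %.6f %.6f",
                  t_ns,
                  rec$acc[, 1], rec$acc[, 2], rec$acc[, 3],
                  rec$gyro[, 1], rec$gyro[, 2], rec$gyro[, 3])
  writeLines(c("# itug IMU log: t_ns ax ay az gx gy gz", body), path)
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Linearly interpolates every channel onto a uniform grid running from the
#' first to the last timestamp at the requested rate. Raw smartphone logs
#' arrive at a nominal ~102.5 Hz with jitter; downstream segmentation and
#' features assume the uniform 100 Hz grid produced here. Linear
#' interpolation is adequate because movement content is well below 5 Hz
#' and the target rate is close to the source rate.
#'
#' @param rec an [imu_recording()].
#' @param rate target rate in Hz (default 100).
#' @return A uniformly sampled [imu_recording()] with `rate` set.
#' @export
resample_recording <- function(rec, rate = 100) {
  n <- length(rec$time)
  if (n < 2)
    stop_itug("itug_insufficient_data",
              "resampling needs at least 2 samples, got %d", n)
  span <- rec$time[n] - rec$time[1]
  grid <- rec$time[1] + seq(0, floor(span * rate + 1e-9)) / rate
  interp <- function(col) stats::approx(rec$time, col, xout = grid,
                                        method = "linear")$y
  imu_recording(grid,
                vapply(seq_len(3), function(j) interp(rec$acc[, j]), grid),
                vapply(seq_len(3), function(j) interp(rec$gyro[, j]), grid),
                rate = rate, axes = rec$axes)
}
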