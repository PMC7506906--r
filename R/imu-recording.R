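#' IMU recording container
#'
#' Holds one session (or one repetition) of trunk-worn inertial sensor data:
#' timestamps in seconds from the start of the recording, triaxial
#' acceleration in m/s^2 and triaxial angular velocity in degrees/s.
#' Axes are either device axes (`x`, `y`, `z`) or, after [align_axes()],
#' anatomical axes `AP` (anterior-posterior), `ML` (mediolateral) and
#' `V` (vertical).
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param acc n x 3 matrix of acceleration (m/s^2).
#' @param gyro n x 3 matrix of angular velocity (deg/s).
#' @param rate nominal sampling rate in Hz, or `NA` for a raw non-uniform
#'   stream.
#' @param axes character vector of length 3 naming the axis convention,
#'   either `c("x","y","z")` (device) or `c("AP","ML","V")` (anatomical).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(time, acc, gyro, rate = NA_real_,
                          axes = c("x", "y", "z")) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  n <- length(time)
  if (ncol(acc) != 3 || ncol(gyro) != 3)
    stop_itug("itug_argument_error", "acc and gyro must have 3 columns")
  if (nrow(acc) != n || nrow(gyro) != n)
    stop_itug("itug_argument_error",
              "acc and gyro must have as many rows as there are timestamps")
  if (n > 1 && any(diff(time) <= 0))
    stop_itug("itug_integrity_error",
              "timestamps must be strictly increasing (first violation at sample %d)",
              which(diff(time) <= 0)[1] + 1L)
  if (!is.na(rate) && n > 1) {
    dt <- diff(time)
    if (max(abs(dt - 1 / rate)) > 1e-9)
      stop_itug("itug_integrity_error",
                "sample spacing is not uniform at 1/%g s", rate)
  }
  colnames(acc) <- colnames(gyro) <- axes
  structure(list(time = as.numeric(time), acc = acc, gyro = gyro,
                 rate = rate, axes = axes),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  dur <- if (length(x$time)) diff(range(x$time)) else 0
  cat(sprintf("<imu_recording> %d samples, %.1f s, rate %s Hz, axes %s\n",
              length(x$time), dur,
              if (is.na(x$rate)) "raw" else format(x$rate),
              paste(x$axes, collapse = "/")))
  invisible(x)
}

#' @export
length.imu_recording <- function(x) length(x$time)

# Extract samples with time inside [from, to); timestamps are re-zeroed and
# the original offset kept as an attribute.
crop_recording <- function(rec, from, to, rezero = TRUE) {
  keep <- rec$time >= from & rec$time < to
  if (!any(keep))
    stop_itug("itug_argument_error", "empty crop interval [%g, %g)", from, to)
  out <- imu_recording(
    if (rezero) rec$time[keep] - rec$time[keep][1] else rec$time[keep],
    rec$acc[keep, , drop = FALSE], rec$gyro[keep, , drop = FALSE],
    rate = rec$rate, axes = rec$axes)
  attr(out, "offset") <- rec$time[keep][1]
  out
}

#' Device-to-anatomical axis map
#'
#' A signed permutation taking device sensor axes to the anatomical frame
#' used throughout the pipeline: index 1 = AP, 2 = ML, 3 = V. Each token is
#' a sign followed by a device axis letter, so `c("+y","-x","+z")` reads
#' "AP is +device-y, ML is -device-x, V is +device-z". A length-6 vector
#' supplies separate maps for the accelerometer (first 3) and gyroscope
#' (last 3).
#'
#' @param tokens character vector of 3 (shared) or 6 (acc then gyro) signed
#'   axis tokens.
#' @return An object of class `axis_map`.
#' @export
axis_map <- function(tokens = c("+x", "+y", "+z")) {
  if (inherits(tokens, "axis_map")) return(tokens)
  if (length(tokens) == 1) tokens <- strsplit(tokens, ",", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  if (!length(tokens) %in% c(3L, 6L))
    stop_itug("itug_config_error", "axis map needs 3 or 6 tokens, got %d",
              length(tokens))
  parse3 <- function(tk) {
    m <- regmatches(tk, regexec("^([+-]?)([xyz])$", tk))
    if (any(lengths(m) != 3))
      stop_itug("itug_config_error", "bad axis token '%s'",
                tk[lengths(m) != 3][1])
    perm <- match(vapply(m, `[`, "", 3), c("x", "y", "z"))
    if (anyDuplicated(perm))
      stop_itug("itug_config_error",
                "axis map must be a permutation; axis '%s' used twice",
                c("x", "y", "z")[perm[duplicated(perm)][1]])
    sgn <- ifelse(vapply(m, `[`, "", 2) == "-", -1, 1)
    list(perm = perm, sign = sgn)
  }
  maps <- if (length(tokens) == 3L) {
    m <- parse3(tokens); list(acc = m, gyro = m)
  } else {
    list(acc = parse3(tokens[1:3]), gyro = parse3(tokens[4:6]))
  }
  structure(maps, class = "axis_map")
}

#' Invert an axis map
#'
#' @param map an [axis_map()].
#' @return The inverse `axis_map`: applying a map and then its inverse
#'   returns the original recording.
#' @export
invert_axis_map <- function(map) {
  map <- axis_map(map)
  inv1 <- function(m) {
    perm <- order(m$perm)
    list(perm = perm, sign = m$sign[perm])
  }
  structure(list(acc = inv1(map$acc), gyro = inv1(map$gyro)),
            class = "axis_map")
}

#' Map device axes to anatomical axes
#'
#' Reorders and signs the acceleration and angular velocity channels so that
#' column 1 is AP, column 2 ML and column 3 V. The smartphone is worn on the
#' lower back in a belt case; the device-to-anatomical map depends on its
#' orientation in the case and is supplied as configuration. Synthetic data
#' is generated directly in anatomical axes, so its map is the identity.
#'
#' @param rec an [imu_recording()].
#' @param map an [axis_map()] (default identity).
#' @return The recording with `axes = c("AP","ML","V")`.
#' @export
align_axes <- function(rec, map = axis_map()) {
  map <- axis_map(map)
  ap <- function(x, m) sweep(x[, m$perm, drop = FALSE], 2, m$sign, `*`)
  out <- imu_recording(rec$time, ap(rec$acc, map$acc), ap(rec$gyro, map$gyro),
                       rate = rec$rate, axes = c("AP", "ML", "V"))
  attr(out, "offset") <- attr(rec, "offset")
  out
}
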