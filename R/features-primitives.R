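# Signal-level feature primitives. All operate on a plain numeric channel
# sampled at `fs` Hz whose first sample is at time 0; `interval` is a
# half-open [start, end) window in the same clock (NULL = whole vector).

slice_idx <- function(n, fs, interval) {
  if (is.null(interval)) return(seq_len(n))
  t <- (seq_len(n) - 1) / fs
  idx <- which(t >= interval[1] & t < interval[2])
  if (length(idx) == 0)
    stop_itug("itug_argument_error", "empty interval [%g, %g)",
              interval[1], interval[2])
  idx
}

#' Root mean square of a signal over an interval
#'
#' @param x numeric channel.
#' @param fs sampling rate (Hz).
#' @param interval optional `c(start, end)` window in seconds.
#' @param demean subtract the interval mean before squaring. Used for
#'   acceleration (removes the gravity component); angular velocity is
#'   taken raw.
#' @return `sqrt(mean(x^2))` over the window.
#' @export
rms <- function(x, fs = 100, interval = NULL, demean = FALSE) {
  x <- x[slice_idx(length(x), fs, interval)]
  if (demean) x <- x - mean(x)
  sqrt(mean(x^2))
}

#' Normalized jerk score of an acceleration segment
#'
#' Dimensionless smoothness measure
#' `NJS = sqrt(T^5 / (2 A^2) * integral(jerk(t)^2 dt))` where jerk is the
#' time derivative of acceleration (central differences), `T` the segment
#' duration and `A` the displacement amplitude obtained by twice
#' integrating the mean-subtracted acceleration (mean subtraction removes
#' constant sensor bias, including gravity, without distorting the pulse
#' shape). A minimum-jerk movement scores `sqrt(360) ~ 18.97`; larger
#' values mean less smooth movement. Invariant under time and amplitude
#' rescaling.
#'
#' @inheritParams rms
#' @return The normalized jerk score.
#' @export
normalized_jerk_score <- function(x, fs = 100, interval = NULL) {
  idx <- slice_idx(length(x), fs, interval)
  if (length(idx) < max(4L, as.integer(0.2 * fs)))
    stop_itug("itug_argument_error", "interval shorter than 0.2 s")
  a <- x[idx] - mean(x[idx])
  h <- 1 / fs
  tt <- (seq_along(a) - 1) * h
  T <- tt[length(tt)]
  v <- pracma::cumtrapz(tt, a)
  s <- pracma::cumtrapz(tt, v)
  A <- max(s) - min(s)
  if (A < .Machine$double.eps^0.5)
    stop_itug("itug_amplitude_error", "zero displacement amplitude")
  j <- pracma::gradient(a, h)
  sqrt(T^5 / (2 * A^2) * pracma::trapz(tt, j^2))
}

#' Normalized angular jerk score of a turning segment
#'
#' The angular analogue of [normalized_jerk_score()]: jerk is the third
#' derivative of the angle (second derivative of angular velocity, by
#' repeated central differences) and the amplitude is the integrated
#' angle.
#'
#' @param w angular velocity channel (deg/s).
#' @inheritParams rms
#' @return The normalized angular jerk score.
#' @export
normalized_angular_jerk_score <- function(w, fs = 100, interval = NULL) {
  idx <- slice_idx(length(w), fs, interval)
  if (length(idx) < max(4L, as.integer(0.2 * fs)))
    stop_itug("itug_argument_error", "interval shorter than 0.2 s")
  wv <- w[idx]
  h <- 1 / fs
  tt <- (seq_along(wv) - 1) * h
  T <- tt[length(tt)]
  A <- abs(pracma::trapz(tt, wv))
  if (A < .Machine$double.eps^0.5)
    stop_itug("itug_amplitude_error", "zero integrated angle")
  j <- pracma::gradient(pracma::gradient(wv, h), h)
  sqrt(T^5 / (2 * A^2) * pracma::trapz(tt, j^2))
}

#' Mean and peak turning velocity
#'
#' @param w angular velocity channel (deg/s).
#' @inheritParams rms
#' @return Named vector `c(mean, peak)` of the absolute angular velocity
#'   over the interval.
#' @export
turn_kinematics <- function(w, fs = 100, interval = NULL) {
  wv <- abs(w[slice_idx(length(w), fs, interval)])
  c(mean = mean(wv), peak = max(wv))
}

# peak prominences for local maxima (standard definition)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    lo <- x[p]
    i <- p
    while (i > 1 && x[i - 1] <= x[p]) { i <- i - 1; lo <- min(lo, x[i]) }
    left <- if (i == 1) min(x[1:p]) else lo
    lo <- x[p]; i <- p; n <- length(x)
    while (i < n && x[i + 1] <= x[p]) { i <- i + 1; lo <- min(lo, x[i]) }
    right <- if (i == n) min(x[p:n]) else lo
    x[p] - max(left, right)
  }, numeric(1))
}

#' Detect step events from vertical acceleration
#'
#' Band-pass filters (0.5-3 Hz, zero-phase) the vertical acceleration over
#' the interval and returns local maxima with prominence of at least
#' `min_prominence` and at least `min_separation` seconds apart (greedy,
#' strongest first).
#'
#' @param x vertical acceleration channel (m/s^2).
#' @inheritParams rms
#' @param min_prominence minimum peak prominence (m/s^2).
#' @param min_separation minimum inter-step time (s).
#' @param band pass band (Hz).
#' @return Numeric vector of step instants (s), possibly empty.
#' @export
detect_steps <- function(x, fs = 100, interval = NULL,
                         min_prominence = 0.3, min_separation = 0.3,
                         band = c(0.5, 3)) {
  idx <- slice_idx(length(x), fs, interval)
  if (length(idx) < as.integer(0.4 * fs))
    stop_itug("itug_argument_error", "interval shorter than 0.4 s")
  # analyse a slightly padded window so a footfall exactly on the interval
  # edge is still a proper local maximum, then keep steps inside [start, end)
  pad <- as.integer(min_separation * fs)
  lo <- max(1L, idx[1] - pad)
  hi <- min(length(x), idx[length(idx)] + pad)
  xf <- bandpass(x[lo:hi], band[1], band[2], fs)
  pk <- which(diff(sign(diff(xf))) < 0) + 1L
  if (length(pk) == 0) return(numeric(0))
  pk <- pk[peak_prominence(xf, pk) >= min_prominence]
  if (length(pk) == 0) return(numeric(0))
  # enforce separation, keeping the strongest peaks
  keep <- logical(length(pk))
  for (i in order(xf[pk], decreasing = TRUE)) {
    if (!any(keep & abs(pk - pk[i]) < min_separation * fs)) keep[i] <- TRUE
  }
  pk <- sort(pk[keep])
  tm <- (lo + pk - 2) / fs
  tm[tm >= (idx[1] - 1) / fs - 0.5 / fs &
       tm < (idx[length(idx)]) / fs - 0.5 / fs]
}

#' Spatio-temporal gait metrics from the walking legs
#'
#' The walk covers a nominal `2 * walk_dist` round trip (chair to cone and
#' back), so gait speed is distance over the summed W1 + W2 duration,
#' average step length is distance per detected step and cadence is steps
#' per second.
#'
#' @param dur_w1,dur_w2 walking-leg durations (s), both positive.
#' @param n_steps number of steps detected over both legs.
#' @param walk_dist one-way walk distance (m), 3 by default.
#' @return Named vector `c(gait_speed, step_length, cadence)`.
#' @export
gait_metrics <- function(dur_w1, dur_w2, n_steps, walk_dist = 3) {
  if (dur_w1 <= 0 || dur_w2 <= 0)
    stop_itug("itug_argument_error", "walking durations must be positive")
  total <- 2 * walk_dist
  if (n_steps < 1)
    stop_itug("itug_gait_error", "no steps: step length undefined")
  c(gait_speed = total / (dur_w1 + dur_w2),
    step_length = total / n_steps,
    cadence = n_steps / (dur_w1 + dur_w2))
}

#' Step regularity from the autocorrelation at the step period
#'
#' Unbiased autocorrelation of the mean-subtracted acceleration; the
#' regularity is the autocorrelation at the dominant step period (the lag
#' maximizing the autocorrelation inside `lag_range`, or within +/-20% of
#' `period_hint` when given) as a percentage of lag 0, clamped to
#' [-100, 100]. A perfectly periodic signal scores 100; white noise
#' scores near 0.
#'
#' @param x acceleration channel.
#' @inheritParams rms
#' @param interval a `c(start, end)` window, or a list of such windows
#'   (e.g. the two walking legs of a TUG); autocorrelations are pooled
#'   across windows, each window mean-subtracted separately.
#' @param lag_range plausible step-period range (s).
#' @param period_hint optional expected step period (s), e.g. 1/cadence.
#' @param min_steps minimum number of step periods the windows must span.
#' @return Regularity in percent.
#' @export
step_regularity <- function(x, fs = 100, interval = NULL,
                            lag_range = c(0.3, 1.0), period_hint = NULL,
                            min_steps = 4) {
  if (!is.list(interval)) interval <- list(interval)
  segs <- lapply(interval, function(iv) {
    xv <- x[slice_idx(length(x), fs, iv)]
    xv - mean(xv)
  })
  if (!is.null(period_hint))
    lag_range <- c(max(lag_range[1], 0.8 * period_hint),
                   min(lag_range[2], 1.2 * period_hint))
  n_tot <- sum(lengths(segs))
  p_ref <- if (is.null(period_hint)) lag_range[1] else period_hint
  lags <- seq(max(2L, as.integer(lag_range[1] * fs)),
              as.integer(lag_range[2] * fs))
  lags <- lags[lags < max(lengths(segs)) - 2]
  if (length(lags) == 0 || n_tot < (min_steps + 1) * p_ref * fs)
    stop_itug("itug_gait_error", "too few steps for regularity")
  r0 <- sum(vapply(segs, function(s) sum(s^2), numeric(1))) / n_tot
  if (r0 == 0) return(0)
  rk <- vapply(lags, function(k) {
    num <- den <- 0
    for (s in segs) {
      n <- length(s)
      if (n - k < 3) next
      num <- num + sum(s[seq_len(n - k)] * s[seq_len(n - k) + k])
      den <- den + (n - k)
    }
    if (den == 0) return(NA_real_)
    num / den
  }, numeric(1))
  rk <- rk[!is.na(rk)]
  if (length(rk) == 0)
    stop_itug("itug_gait_error", "windows shorter than the step period")
  max(min(100 * max(rk) / r0, 100), -100)
}
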