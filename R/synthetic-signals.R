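# Synthetic iTUG signal generator. One trial is built phase by phase in
# anatomical axes (AP/ML/V) on a uniform grid: quiet sitting, Sit-to-Walk
# (minimum-jerk forward acceleration plus a trunk-pitch angular velocity
# pulse), walk-out over 3 m with step oscillations at the subject's
# cadence, a ~180 deg first turn (half-sine yaw velocity pulse), walk-back,
# and Turn-to-Sit (second ~180 deg yaw pulse overlapping a sit-down pitch
# pulse), then quiet sitting again. All events are recorded as ground truth
# so segmentation and feature recovery can be scored exactly.

# minimum-jerk acceleration profile for unit displacement over unit time
minjerk_acc <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

#' Simulate one iTUG repetition
#'
#' @param profile a one-row data.frame (or list) with the kinematic fields
#'   produced by [simulate_cohort()]: `gait_speed`, `cadence`, `turn_peak`,
#'   `stw_duration`, `sit_duration`, `step_amp`.
#' @param repetition repetition index (recorded in the ground truth).
#' @param seed integer seed for the repetition's noise and jitter.
#' @param noise_acc,noise_gyro additive white-noise SD on acceleration
#'   (m/s^2) and angular velocity (deg/s).
#' @param rep_jitter relative SD of within-subject repetition-to-repetition
#'   variation applied to the kinematic parameters.
#' @param fs sampling rate (Hz).
#' @param lead,tail quiet-sitting padding before and after the trial (s).
#' @param walk_dist chair-to-cone distance in metres (one way).
#' @param turn_angle nominal turn magnitude in degrees.
#' @return A list with `recording` (an [imu_recording()] in anatomical
#'   axes) and `truth`, which holds the phase boundaries (`stw_start`,
#'   `stw_end`, `ft_start`, `ft_end`, `tts_turn_start`, `tts_turn_end`,
#'   `sit_end`, all in seconds from recording start), step instants per
#'   phase, true turn peak/mean velocities and angles, and the jittered
#'   kinematic parameters.
#' @export
simulate_trial <- function(profile, repetition = 1, seed = 1,
                           noise_acc = 0.15, noise_gyro = 3,
                           rep_jitter = 0.03, fs = 100,
                           lead = 2, tail = 2,
                           walk_dist = 3, turn_angle = 180) {
  pr <- as.list(profile)
  kin <- c("gait_speed", "cadence", "turn_peak", "stw_duration",
           "sit_duration", "step_amp")
  miss <- setdiff(kin, names(pr))
  if (length(miss))
    stop_itug("itug_argument_error", "profile lacks kinematic field(s): %s",
              paste(miss, collapse = ", "))
  if (any(unlist(pr[kin]) <= 0))
    stop_itug("itug_argument_error", "kinematic parameters must be positive")

  with_seed(seed, {
    jit <- function(x) x * (1 + rep_jitter * stats::rnorm(1))
    v <- jit(pr$gait_speed); cad <- jit(pr$cadence)
    p_ft <- jit(pr$turn_peak); p_tts <- 0.92 * jit(pr$turn_peak)
    d_stw <- jit(pr$stw_duration); d_sit <- jit(pr$sit_duration)
    amp <- jit(pr$step_amp)
    d_w <- walk_dist / v
    t_ft <- turn_angle * pi / (2 * p_ft)    # half-sine pulse duration
    t_tts <- turn_angle * pi / (2 * p_tts)

    stw0 <- lead;            stw1 <- stw0 + d_stw
    w1a <- stw1;             w1b <- w1a + d_w
    fta <- w1b;              ftb <- fta + t_ft
    w2a <- ftb;              w2b <- w2a + d_w
    tta <- w2b;              ttb <- tta + t_tts
    sit0 <- ttb - 0.3 * d_sit; sit1 <- sit0 + d_sit
    total <- sit1 + tail
    n <- floor(total * fs) + 1L
    t <- (seq_len(n) - 1L) / fs

    acc <- matrix(stats::rnorm(3 * n, 0, noise_acc), n, 3)
    gyro <- matrix(stats::rnorm(3 * n, 0, noise_gyro), n, 3)
    acc[, 3] <- acc[, 3] + 9.81   # gravity on the vertical axis

    within <- function(a, b) t >= a & t < b
    add <- function(M, j, mask, x) { M[mask, j] <- M[mask, j] + x; M }

    # Sit-to-Walk: forward minimum-jerk acceleration + trunk pitch pulse
    m <- within(stw0, stw1); tau <- (t[m] - stw0) / d_stw
    acc <- add(acc, 1, m, 0.35 / d_stw^2 * minjerk_acc(tau))
    gyro <- add(gyro, 2, m, 50 * sin(pi * tau))

    # walking legs: step oscillations, first footfall at leg start; the
    # trunk pitches (ML) and yaws (V) with each step
    walk_leg <- function(a, b) {
      m <- within(a, b); ph <- 2 * pi * cad * (t[m] - a)
      acc <<- add(acc, 3, m, amp * cos(ph))
      acc <<- add(acc, 1, m, 0.5 * amp * cos(ph))
      gyro <<- add(gyro, 3, m, 8 * cos(ph))
      gyro <<- add(gyro, 2, m, 6 * sin(ph))
      a + seq(0, by = 1 / cad, length.out = floor((b - a) * cad - 1e-9) + 1L)
    }
    steps_w1 <- walk_leg(w1a, w1b)
    steps_w2 <- walk_leg(w2a, w2b)

    # turns: half-sine yaw velocity pulse + slower stepping (people step
    # through a turn, so pitch/roll keep oscillating)
    turn <- function(a, b, peak, sgn) {
      m <- within(a, b); tau <- (t[m] - a) / (b - a)
      gyro <<- add(gyro, 3, m, sgn * peak * sin(pi * tau))
      ph <- 2 * pi * 0.75 * cad * (t[m] - a)
      acc <<- add(acc, 3, m, 0.6 * amp * cos(ph))
      acc <<- add(acc, 1, m, 0.3 * amp * cos(ph))
      gyro <<- add(gyro, 2, m, 8 * sin(ph))
      gyro <<- add(gyro, 1, m, 5 * cos(ph))
      a + seq(0, by = 1 / (0.75 * cad),
              length.out = floor((b - a) * 0.75 * cad - 1e-9) + 1L)
    }
    steps_ft <- turn(fta, ftb, p_ft, +1)
    steps_tts <- turn(tta, ttb, p_tts, -1)

    # sit-down: backward minimum-jerk deceleration + pitch pulse
    m <- within(sit0, sit1); tau <- (t[m] - sit0) / d_sit
    acc <- add(acc, 1, m, -0.35 / d_sit^2 * minjerk_acc(tau))
    gyro <- add(gyro, 2, m, 45 * sin(pi * tau))

    rec <- imu_recording(t, acc, gyro, rate = fs, axes = c("AP", "ML", "V"))
    truth <- list(
      repetition = repetition,
      boundaries = c(stw_start = stw0, stw_end = stw1, ft_start = fta,
                     ft_end = ftb, tts_turn_start = tta, tts_turn_end = ttb,
                     sit_end = sit1),
      steps = list(w1 = steps_w1, w2 = steps_w2, ft = steps_ft,
                   tts = steps_tts),
      turn_peak = c(ft = p_ft, tts = p_tts),
      turn_mean = c(ft = 2 * p_ft / pi, tts = 2 * p_tts / pi),
      turn_angle = c(ft = turn_angle, tts = -turn_angle),
      params = list(gait_speed = v, cadence = cad, step_amp = amp,
                    stw_duration = d_stw, sit_duration = d_sit,
                    walk_dist = walk_dist),
      cbms = if (!is.null(pr$cbms)) pr$cbms else NA_real_)
    list(recording = rec, truth = truth)
  })
}

#' Simulate a five-repetition iTUG session
#'
#' Concatenates `n_rep` trials separated by quiet-sitting rest gaps, as in
#' the five-repetitions-with-30-s-breaks protocol. Ground-truth boundaries
#' are reported in session time.
#'
#' @param profile subject profile row, as for [simulate_trial()].
#' @param seed integer master seed; each repetition gets its own sub-seed.
#' @param n_rep number of repetitions (default 5).
#' @param gap rest duration between repetitions in seconds (default 30).
#' @param ... further arguments passed to [simulate_trial()].
#' @param noise_acc,noise_gyro,fs as in [simulate_trial()].
#' @return A list with `recording` (the whole session) and `truth`, a list
#'   of per-repetition ground truths whose boundary and step times are
#'   offset to session time (each also keeps `offset`, the session time of
#'   the repetition's first sample).
#' @export
simulate_session <- function(profile, seed = 1, n_rep = 5, gap = 30,
                             noise_acc = 0.15, noise_gyro = 3, fs = 100,
                             ...) {
  seeds <- spawn_seeds(seed, n_rep + 1L)
  trials <- lapply(seq_len(n_rep), function(r)
    simulate_trial(profile, repetition = r, seed = seeds[r],
                   noise_acc = noise_acc, noise_gyro = noise_gyro, fs = fs,
                   ...))
  n_gap <- as.integer(round(gap * fs))
  gap_block <- function(gseed) with_seed(gseed, {
    a <- matrix(stats::rnorm(3 * n_gap, 0, noise_acc), n_gap, 3)
    a[, 3] <- a[, 3] + 9.81
    list(acc = a, gyro = matrix(stats::rnorm(3 * n_gap, 0, noise_gyro),
                                n_gap, 3))
  })
  gap_seeds <- with_seed(seeds[n_rep + 1L],
                         sample.int(.Machine$integer.max - 1L, n_rep))
  acc <- NULL; gyro <- NULL; offsets <- numeric(n_rep); pos <- 0L
  for (r in seq_len(n_rep)) {
    rec <- trials[[r]]$recording
    offsets[r] <- pos / fs
    acc <- rbind(acc, rec$acc); gyro <- rbind(gyro, rec$gyro)
    pos <- pos + length(rec$time)
    if (r < n_rep) {
      g <- gap_block(gap_seeds[r])
      acc <- rbind(acc, g$acc); gyro <- rbind(gyro, g$gyro)
      pos <- pos + n_gap
    }
  }
  t <- (seq_len(nrow(acc)) - 1L) / fs
  truth <- lapply(seq_len(n_rep), function(r) {
    tr <- trials[[r]]$truth
    tr$offset <- offsets[r]
    tr$boundaries <- tr$boundaries + offsets[r]
    tr$steps <- lapply(tr$steps, function(s) s + offsets[r])
    tr
  })
  list(recording = imu_recording(t, acc, gyro, rate = fs,
                                 axes = c("AP", "ML", "V")),
       truth = truth)
}
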