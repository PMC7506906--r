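# Session splitting and phase segmentation of single TUG repetitions.
# The phase scheme: Sit-to-Walk (StW), walk-out (W1), First Turn (FT),
# walk-back (W2) and Turn-to-Sit (TtS, which contains a turning
# sub-interval followed by the sit-down). Turns are found on the vertical
# (yaw) angular velocity; the stand-up onset and sit-down end on the
# mediolateral (pitch) angular velocity and anterior-posterior
# acceleration. All intervals are half-open [start, end) in seconds from
# repetition start.

#' Segmentation configuration
#'
#' All detection thresholds in one place. The defaults are standard
#' choices for trunk-worn IMU analysis of the TUG and can be overridden
#' per call.
#'
#' @param lp_cutoff low-pass cut-off (Hz) applied to the yaw angular
#'   velocity before turn detection (zero-phase).
#' @param lp_transition low-pass cut-off (Hz) for the transition channels
#'   (ML angular velocity, AP acceleration). Wider than the turn filter:
#'   sit-to-stand pulses are brief, and a narrow zero-phase filter smears
#'   them backwards in time, biasing the detected onset early.
#' @param turn_threshold yaw angular velocity (deg/s) that seeds a turn
#'   candidate.
#' @param turn_edge_frac,turn_edge_min each candidate is extended outward
#'   to the nearest crossing of `max(turn_edge_min, turn_edge_frac * peak)`
#'   (deg/s).
#' @param min_turn_angle minimum integrated angle (deg) for a candidate to
#'   count as a turn.
#' @param onset_mult transition onset threshold as a multiple of the
#'   quiescent-baseline SD.
#' @param onset_sustain minimum duration (s) the threshold must be
#'   exceeded.
#' @param onset_floor_frac absolute floor on the transition threshold as a
#'   fraction of the channel's peak amplitude (guards the noiseless case).
#' @param baseline_window duration (s) of the quiet lead-in used to
#'   estimate the quiescent baseline.
#' @param activity_threshold moving-SD of gyro magnitude (deg/s) above
#'   which a sample counts as active when splitting a session.
#' @param activity_window moving-SD window (s).
#' @param min_gap minimum quiescence (s) separating two repetitions.
#' @param pad context (s) retained around each repetition.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(lp_cutoff = 1.5, lp_transition = 5,
                       turn_threshold = 45,
                       turn_edge_frac = 0.1, turn_edge_min = 5,
                       min_turn_angle = 90,
                       onset_mult = 3, onset_sustain = 0.2,
                       onset_floor_frac = 0.02, baseline_window = 0.8,
                       activity_threshold = 8, activity_window = 1,
                       min_gap = 5, pad = 1) {
  structure(as.list(environment()), class = "seg_config")
}

#' Split a session into repetitions
#'
#' Detects activity as the sum over the three gyro axes of a 1 s moving SD
#' of the 6 Hz low-passed angular velocity; samples above threshold are
#' active, and contiguous active blocks separated by at least `min_gap`
#' seconds of quiescence become repetitions, each returned with `pad`
#' seconds of context on both sides. Summing per-axis SDs (rather than
#' taking the SD of the magnitude) keeps steady walking active: its ML and
#' yaw oscillations are in phase quadrature, which leaves the magnitude
#' almost constant.
#'
#' @param rec an axis-aligned, uniformly sampled [imu_recording()].
#' @param config a [seg_config()].
#' @return List of [imu_recording()] objects, each with an `offset`
#'   attribute giving the session time of its first sample.
#' @export
split_repetitions <- function(rec, config = seg_config()) {
  fs <- rec$rate
  if (is.na(fs))
    stop_itug("itug_argument_error", "recording must be resampled first")
  gsm <- apply(rec$gyro, 2, lowpass, cutoff = 6, fs = fs)
  act_level <- rowSums(vapply(seq_len(3), function(j)
    moving_sd(gsm[, j], config$activity_window * fs),
    numeric(nrow(gsm))))
  act <- act_level > config$activity_threshold
  runs <- true_runs(act)
  if (nrow(runs) == 0)
    stop_itug("itug_no_activity", "no activity detected in recording")
  # merge blocks separated by less than min_gap of quiescence
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if ((runs[i, "start"] - merged[nrow(merged), "end"]) / fs < config$min_gap) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  lapply(seq_len(nrow(merged)), function(i) {
    from <- max(rec$time[1], rec$time[merged[i, "start"]] - config$pad)
    to <- min(rec$time[length(rec$time)] + 1 / fs,
              rec$time[merged[i, "end"]] + config$pad)
    crop_recording(rec, from, to)
  })
}

#' Detect turns from yaw angular velocity
#'
#' The vertical-axis angular velocity is zero-phase low-pass filtered and
#' median-detrended; excursions beyond `turn_threshold` seed candidates
#' which are extended outward to the nearest crossing of
#' `max(turn_edge_min, turn_edge_frac * peak)`, merged when overlapping,
#' and kept when the integrated angle reaches `min_turn_angle`.
#'
#' @param rec a single-repetition [imu_recording()] in anatomical axes.
#' @param config a [seg_config()].
#' @return data.frame with one row per detected turn: `start`, `end` (s),
#'   `peak` and `mean_vel` (deg/s, magnitudes of the filtered signal) and
#'   signed integrated `angle` (deg). May have zero rows.
#' @export
detect_turns <- function(rec, config = seg_config()) {
  fs <- rec$rate
  w <- lowpass(rec$gyro[, "V"], config$lp_cutoff, fs)
  w <- w - stats::median(w)
  n <- length(w)
  cand <- true_runs(abs(w) > config$turn_threshold)
  if (nrow(cand) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      peak = numeric(0), mean_vel = numeric(0),
                      angle = numeric(0)))
  iv <- t(apply(cand, 1, function(r) {
    pk <- max(abs(w[r[1]:r[2]]))
    thr <- max(config$turn_edge_min, config$turn_edge_frac * pk)
    lo <- r[1]; while (lo > 1 && abs(w[lo - 1]) > thr) lo <- lo - 1
    hi <- r[2]; while (hi < n && abs(w[hi + 1]) > thr) hi <- hi + 1
    c(lo, hi)
  }))
  # merge overlapping extended intervals
  ord <- order(iv[, 1]); iv <- iv[ord, , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= merged[nrow(merged), 2]) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
  }
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged[i, 1]:merged[i, 2]
    data.frame(start = rec$time[merged[i, 1]],
               end = rec$time[merged[i, 2]] + 1 / fs,
               peak = max(abs(w[idx])),
               mean_vel = mean(abs(w[idx])),
               angle = pracma::trapz(rec$time[idx], w[idx]))
  }))
  out[abs(out$angle) >= config$min_turn_angle, , drop = FALSE]
}

#' Detect the stand-up onset and sit-down end
#'
#' Estimates a quiescent baseline from the quiet lead-in, then finds the
#' earliest and latest times at which the low-pass-filtered mediolateral
#' angular velocity or mean-subtracted anterior-posterior acceleration
#' exceeds `onset_mult` times its baseline SD for at least `onset_sustain`
#' seconds.
#'
#' @param rec a single-repetition [imu_recording()] in anatomical axes.
#' @param config a [seg_config()].
#' @return List with `onset` and `sit_end` (seconds).
#' @export
detect_transitions <- function(rec, config = seg_config()) {
  fs <- rec$rate
  ml <- lowpass(rec$gyro[, "ML"], config$lp_transition, fs)
  ap <- lowpass(rec$acc[, "AP"] - mean(rec$acc[, "AP"]), config$lp_transition, fs)
  nb <- max(3L, as.integer(config$baseline_window * fs))
  if (nb >= length(ml))
    stop_itug("itug_baseline_error", "recording shorter than baseline window")
  base <- seq_len(nb)
  # lead-in must actually be quiet relative to the most active stretch
  act <- moving_sd(ml, as.integer(0.5 * fs))
  if (stats::sd(ml[base]) > 0.5 * max(act))
    stop_itug("itug_baseline_error",
              "no quiescent baseline in the first %.1f s", config$baseline_window)
  sustain <- max(1L, as.integer(config$onset_sustain * fs))
  hits <- function(x) {
    thr <- max(config$onset_mult * stats::sd(x[base]),
               config$onset_floor_frac * max(abs(x)))
    runs <- true_runs(abs(x) > thr)
    runs[runs[, "end"] - runs[, "start"] + 1L >= sustain, , drop = FALSE]
  }
  h <- rbind(hits(ml), hits(ap))
  if (nrow(h) == 0)
    stop_itug("itug_no_activity", "no movement exceeds the onset threshold")
  list(onset = rec$time[min(h[, "start"])],
       sit_end = rec$time[max(h[, "end"])] + 1 / fs)
}

#' Segment one repetition into the five iTUG phases
#'
#' Requires exactly two major turns. The first detected turn is the First
#' Turn; the second is the turning sub-interval of Turn-to-Sit. Sit-to-Walk
#' runs from the stand-up onset to the first step event, W1 and W2 fill the
#' gaps between transitions and turns, and Turn-to-Sit extends from the
#' second turn's start to the sit-down end.
#'
#' @param rec a single-repetition [imu_recording()] in anatomical axes.
#' @param config a [seg_config()].
#' @return An object of class `trial_segmentation`: data.frame `phases`
#'   (phase, start, end) for StW, W1, FT, W2, TtS plus the `tts_turn` and
#'   `tts_sit` sub-intervals and the `total` interval.
#' @export
segment_trial <- function(rec, config = seg_config()) {
  turns <- detect_turns(rec, config)
  if (nrow(turns) != 2)
    stop_itug("itug_segmentation_error",
              "expected exactly 2 turns with |angle| >= %g deg, found %d",
              config$min_turn_angle, nrow(turns))
  tr <- detect_transitions(rec, config)
  if (!(tr$onset < turns$start[1] && turns$end[2] <= tr$sit_end))
    stop_itug("itug_segmentation_error",
              "turns do not lie between stand-up onset and sit-down end")
  steps <- detect_steps(rec$acc[, "V"], rec$rate,
                        interval = c(tr$onset, turns$start[1]))
  stw_end <- if (length(steps)) {
    steps[1]
  } else {
    warning("no step detected between stand-up and first turn; ",
            "using interval midpoint", call. = FALSE)
    (tr$onset + turns$start[1]) / 2
  }
  phases <- data.frame(
    phase = c("StW", "W1", "FT", "W2", "TtS"),
    start = c(tr$onset, stw_end, turns$start[1], turns$end[1],
              turns$start[2]),
    end = c(stw_end, turns$start[1], turns$end[1], turns$start[2],
            tr$sit_end),
    stringsAsFactors = FALSE)
  if (any(phases$end < phases$start) || is.unsorted(phases$start))
    stop_itug("itug_segmentation_error", "phase intervals out of order")
  structure(list(phases = phases,
                 tts_turn = c(turns$start[2], turns$end[2]),
                 tts_sit = c(turns$end[2], tr$sit_end),
                 total = c(tr$onset, tr$sit_end),
                 turns = turns),
            class = "trial_segmentation")
}

#' @export
print.trial_segmentation <- function(x, ...) {
  cat("<trial_segmentation>\n")
  p <- x$phases
  cat(sprintf("  %-4s %7.2f - %7.2f s\n", p$phase, p$start, p$end), sep = "")
  cat(sprintf("  total %.2f s\n", diff(x$total)))
  invisible(x)
}

# Interval lookup used by the feature extractor.
seg_interval <- function(seg, which) {
  p <- seg$phases
  switch(which,
         StW = c(p$start[1], p$end[1]),
         W1 = c(p$start[2], p$end[2]),
         FT = c(p$start[3], p$end[3]),
         W2 = c(p$start[4], p$end[4]),
         TtS = c(p$start[5], p$end[5]),
         tts_turn = seg$tts_turn,
         tts_sit = seg$tts_sit,
         total = seg$total,
         stop_itug("itug_argument_error", "unknown interval '%s'", which))
}
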