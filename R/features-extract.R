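# The 78-feature iTUG catalogue: durations, intensity (RMS), signal range,
# smoothness (normalized jerk scores), turn kinematics, step counts and
# spatio-temporal gait metrics, organised as categories x phases.

#' The iTUG feature manifest
#'
#' Enumerates the 78 signal features computed by [extract_features()], in
#' output order, with category, phase, axis, units and — where the feature
#' has a conventional printed label — that label. Phase codes: `stw`
#' (Sit-to-Walk), `w` (walk, both legs), `w1`/`w2` (walk-out/walk-back),
#' `ft` (First Turn), `tts` (Turn-to-Sit), `tts_turn`/`tts_sit` (its
#' turning and sitting sub-intervals), `total`.
#'
#' @return A data.frame with columns `name`, `category`, `phase`, `axis`,
#'   `units`, `label`.
#' @export
feature_manifest <- function() {
  rws <- list()
  add <- function(name, category, phase, axis = NA, units = "", label = NA)
    rws[[length(rws) + 1L]] <<- data.frame(
      name = name, category = category, phase = phase, axis = axis,
      units = units, label = label, stringsAsFactors = FALSE)
  for (ph in c("stw", "w", "w1", "w2", "ft", "tts", "tts_turn", "tts_sit",
               "total"))
    add(paste0("dur_", ph), "duration", ph, units = "s")
  for (ph in c("stw", "w", "ft", "tts", "total"))
    for (ax in c("ap", "ml", "v"))
      add(sprintf("rms_acc_%s_%s", ax, ph), "rms_acc", ph, ax, "m/s^2")
  for (ph in c("stw", "w", "ft", "tts", "total"))
    for (ax in c("ap", "ml", "v"))
      add(sprintf("rms_gyro_%s_%s", ax, ph), "rms_gyro", ph, ax, "deg/s")
  for (ph in c("stw", "w", "ft", "tts", "total"))
    for (ax in c("ap", "ml", "v"))
      add(sprintf("range_gyro_%s_%s", ax, ph), "range_gyro", ph, ax, "deg/s")
  for (ax in c("ap", "ml", "v"))
    add(sprintf("range_acc_%s_w", ax), "range_acc", "w", ax, "m/s^2")
  for (ph in c("w", "stw"))
    for (ax in c("ap", "ml", "v"))
      add(sprintf("njs_acc_%s_%s", ax, ph), "njs", ph, ax, "")
  add("najs_ft", "najs", "ft", "v", "")
  add("najs_tts", "najs", "tts_turn", "v", "")
  add("turn_mean_vel_ft", "turn_vel", "ft", "v", "deg/s")
  add("turn_peak_vel_ft", "turn_vel", "ft", "v", "deg/s")
  add("turn_mean_vel_tts", "turn_vel", "tts_turn", "v", "deg/s")
  add("turn_peak_vel_tts", "turn_vel", "tts_turn", "v", "deg/s")
  add("steps_w", "steps", "w", units = "count")
  add("steps_ft", "steps", "ft", units = "count")
  add("steps_tts", "steps", "tts", units = "count")
  add("steps_total", "steps", "total", units = "count")
  add("step_length_avg", "gait", "w", units = "m")
  add("gait_speed", "gait", "w", units = "m/s")
  add("cadence", "gait", "w", units = "steps/s")
  add("step_regularity_v", "regularity", "w", "v", "%")
  add("step_regularity_ap", "regularity", "w", "ap", "%")
  out <- do.call(rbind, rws)
  labels <- c(
    dur_stw = "StW duration [s]", dur_w = "Walk duration [s]",
    dur_ft = "Turn duration [s]", dur_tts = "TtS duration [s]",
    dur_tts_turn = "TtS turning duration [s]",
    dur_total = "Total duration [s]",
    turn_mean_vel_ft = "Mean velocity first turn [deg/s]",
    turn_peak_vel_ft = "Peak velocity first turn [deg/s]",
    turn_mean_vel_tts = "Mean velocity TtS [deg/s]",
    turn_peak_vel_tts = "Peak velocity TtS [deg/s]",
    najs_ft = "NAJS first turn", najs_tts = "NAJS TtS",
    rms_acc_ap_w = "RMS acc. walking AP [m/s^2]",
    rms_acc_v_w = "RMS acc. walking V [m/s^2]",
    rms_gyro_v_w = "RMS angular velocity walking V [deg/s]",
    range_gyro_v_w = "Range angular velocity walking V [deg/s]",
    njs_acc_ap_w = "Jerk score walking AP",
    njs_acc_v_w = "Jerk score walking V",
    steps_total = "Total number of steps",
    steps_ft = "Number of steps in first turn",
    step_length_avg = "Average step length [m]",
    gait_speed = "Gait speed [m/s]",
    step_regularity_v = "Step regularity V [%]")
  out$label <- labels[out$name]
  stopifnot(nrow(out) == 78L, !anyDuplicated(out$name))
  out
}

#' Extract the 78-feature vector from one segmented repetition
#'
#' Computes every entry of [feature_manifest()] from a single-repetition
#' recording and its segmentation. Angular velocity is smoothed at 6 Hz
#' and acceleration at 10 Hz (zero-phase) before the kinematic and
#' smoothness features, which suppresses broadband sensor noise without
#' touching movement content; RMS and range are computed on the unsmoothed
#' channels (acceleration mean-subtracted per segment, angular velocity
#' raw). A feature whose computation fails is reported as `NA` with the
#' reason collected in the `failures` attribute; more than
#' `max_missing_frac` missing features is an error.
#'
#' @param rec a single-repetition [imu_recording()] in anatomical axes.
#' @param seg the matching [segment_trial()] result.
#' @param walk_dist one-way walk distance (m).
#' @param max_missing_frac maximum tolerated fraction of missing features.
#' @return Named numeric vector of length 78 (class `itug_features`).
#' @export
extract_features <- function(rec, seg, walk_dist = 3,
                             max_missing_frac = 0.2) {
  fs <- rec$rate
  man <- feature_manifest()
  out <- stats::setNames(rep(NA_real_, nrow(man)), man$name)
  failures <- character(0)
  put <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e); NA_real_
    })
    out[[name]] <<- as.numeric(v)[1]
  }
  iv <- function(ph) seg_interval(seg, switch(ph,
    stw = "StW", w1 = "W1", w2 = "W2", ft = "FT", tts = "TtS",
    tts_turn = "tts_turn", tts_sit = "tts_sit", total = "total"))
  axcol <- c(ap = 1L, ml = 2L, v = 3L)
  gy_sm <- apply(rec$gyro, 2, lowpass, cutoff = 6, fs = fs)
  ac_sm <- apply(rec$acc, 2, lowpass, cutoff = 10, fs = fs)

  # durations (W = W1 + W2, non-contiguous)
  for (ph in c("stw", "w1", "w2", "ft", "tts", "tts_turn", "tts_sit",
               "total"))
    put(paste0("dur_", ph), diff(iv(ph)))
  out[["dur_w"]] <- out[["dur_w1"]] + out[["dur_w2"]]

  # RMS and range; the walk aggregates samples from both legs
  samp <- function(M, ax, ph) {
    if (ph == "w") {
      c(M[slice_idx(nrow(M), fs, iv("w1")), axcol[ax]],
        M[slice_idx(nrow(M), fs, iv("w2")), axcol[ax]])
    } else M[slice_idx(nrow(M), fs, iv(ph)), axcol[ax]]
  }
  for (ph in c("stw", "w", "ft", "tts", "total")) {
    for (ax in c("ap", "ml", "v")) {
      put(sprintf("rms_acc_%s_%s", ax, ph),
          rms(samp(rec$acc, ax, ph), fs, demean = TRUE))
      put(sprintf("rms_gyro_%s_%s", ax, ph),
          rms(samp(rec$gyro, ax, ph), fs))
      put(sprintf("range_gyro_%s_%s", ax, ph),
          diff(range(samp(rec$gyro, ax, ph))))
    }
  }
  for (ax in c("ap", "ml", "v"))
    put(sprintf("range_acc_%s_w", ax), diff(range(samp(rec$acc, ax, "w"))))

  # smoothness: walking jerk scores averaged over the two legs
  for (ax in c("ap", "ml", "v")) {
    put(sprintf("njs_acc_%s_w", ax),
        mean(c(normalized_jerk_score(ac_sm[, axcol[ax]], fs, iv("w1")),
               normalized_jerk_score(ac_sm[, axcol[ax]], fs, iv("w2")))))
    put(sprintf("njs_acc_%s_stw", ax),
        normalized_jerk_score(ac_sm[, axcol[ax]], fs, iv("stw")))
  }
  put("najs_ft", normalized_angular_jerk_score(gy_sm[, 3], fs, iv("ft")))
  put("najs_tts",
      normalized_angular_jerk_score(gy_sm[, 3], fs, iv("tts_turn")))

  # turn kinematics on the smoothed yaw channel
  put("turn_mean_vel_ft", turn_kinematics(gy_sm[, 3], fs, iv("ft"))["mean"])
  put("turn_peak_vel_ft", turn_kinematics(gy_sm[, 3], fs, iv("ft"))["peak"])
  put("turn_mean_vel_tts",
      turn_kinematics(gy_sm[, 3], fs, iv("tts_turn"))["mean"])
  put("turn_peak_vel_tts",
      turn_kinematics(gy_sm[, 3], fs, iv("tts_turn"))["peak"])

  # steps and gait metrics
  vacc <- rec$acc[, 3]
  st_w1 <- tryCatch(detect_steps(vacc, fs, iv("w1")),
                    error = function(e) numeric(0))
  st_w2 <- tryCatch(detect_steps(vacc, fs, iv("w2")),
                    error = function(e) numeric(0))
  st_ft <- tryCatch(detect_steps(vacc, fs, iv("ft")),
                    error = function(e) numeric(0))
  st_tts <- tryCatch(detect_steps(vacc, fs, iv("tts")),
                     error = function(e) numeric(0))
  out[["steps_w"]] <- length(st_w1) + length(st_w2)
  out[["steps_ft"]] <- length(st_ft)
  out[["steps_tts"]] <- length(st_tts)
  out[["steps_total"]] <- out[["steps_w"]] + out[["steps_ft"]] +
    out[["steps_tts"]]
  put("gait_speed", gait_metrics(out[["dur_w1"]], out[["dur_w2"]],
                                 out[["steps_w"]], walk_dist)["gait_speed"])
  put("step_length_avg",
      gait_metrics(out[["dur_w1"]], out[["dur_w2"]], out[["steps_w"]],
                   walk_dist)["step_length"])
  put("cadence", gait_metrics(out[["dur_w1"]], out[["dur_w2"]],
                              out[["steps_w"]], walk_dist)["cadence"])
  hint <- if (length(st_w1) > 1) mean(diff(st_w1)) else NULL
  put("step_regularity_v",
      step_regularity(vacc, fs, list(iv("w1"), iv("w2")),
                      period_hint = hint))
  put("step_regularity_ap",
      step_regularity(rec$acc[, 1], fs, list(iv("w1"), iv("w2")),
                      period_hint = hint))

  # drop the helper columns used above (w1/w2 durations stay in the
  # manifest; nothing extra was added)
  n_missing <- sum(is.na(out))
  if (n_missing > max_missing_frac * length(out))
    stop_itug("itug_feature_error",
              "%d of %d features missing (limit %.0f%%): %s",
              n_missing, length(out), 100 * max_missing_frac,
              paste(utils::head(names(failures), 5), collapse = ", "))
  structure(out, failures = failures, class = c("itug_features", "numeric"))
}

#' Average feature vectors across repetitions
#'
#' Per-feature arithmetic mean over the (typically five) repetitions,
#' ignoring missing values; a feature missing in every repetition stays
#' missing.
#'
#' @param vectors list of feature vectors from [extract_features()], all
#'   with identical names.
#' @return Named numeric vector of the same length.
#' @export
average_features <- function(vectors) {
  if (length(vectors) < 1)
    stop_itug("itug_argument_error", "need at least one feature vector")
  nm <- names(vectors[[1]])
  for (v in vectors)
    if (!identical(names(v), nm))
      stop_itug("itug_schema_error", "feature names differ across repetitions")
  M <- do.call(rbind, lapply(vectors, as.numeric))
  stats::setNames(colMeans(M, na.rm = TRUE), nm)
}
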