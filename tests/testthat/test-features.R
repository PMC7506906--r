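# Feature primitives and the 78-feature extractor.

test_that("rms matches closed forms and brute force", {
  fs <- 100
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)   # whole periods of a 1 Hz sine
  x <- 2.5 * sin(2 * pi * t)
  expect_equal(rms(x, fs), 2.5 / sqrt(2), tolerance = 1e-3)
  expect_equal(rms(rep(3.7, 50), fs, demean = TRUE), 0)
  set.seed(1)
  z <- rnorm(400)
  expect_equal(rms(z, fs), sqrt(mean(z^2)), tolerance = 1e-12)
  expect_error(rms(z, fs, interval = c(10, 11)),
               class = "itug_argument_error")
})

test_that("normalized jerk score equals sqrt(360) for minimum-jerk movement", {
  for (T in c(1, 2)) {
    a <- minjerk_acc_samples(T = T, fs = 100)
    expect_equal(normalized_jerk_score(a, 100), sqrt(360),
                 tolerance = 0.02 * sqrt(360))
  }
  # amplitude rescaling leaves it unchanged
  a <- minjerk_acc_samples(T = 2, fs = 100)
  expect_equal(normalized_jerk_score(5 * a, 100),
               normalized_jerk_score(a, 100), tolerance = 1e-9)
  # time rescaling (same profile over half the duration) too
  a_fast <- minjerk_acc_samples(T = 1, fs = 100, A = 1)
  expect_equal(normalized_jerk_score(a_fast, 100),
               normalized_jerk_score(a, 100),
               tolerance = 0.02 * sqrt(360))
  expect_error(normalized_jerk_score(rep(0, 100), 100),
               class = "itug_amplitude_error")
})

test_that("normalized angular jerk score mirrors the linear version", {
  w <- minjerk_omega_samples(T = 2, fs = 100, angle = 180)
  expect_equal(normalized_angular_jerk_score(w, 100), sqrt(360),
               tolerance = 0.02 * sqrt(360))
  # doubling the turn angle with the same shape changes nothing
  expect_equal(normalized_angular_jerk_score(2 * w, 100),
               normalized_angular_jerk_score(w, 100), tolerance = 1e-9)
  # added ripple strictly increases the score
  t <- seq(0, 2, by = 0.01)
  ripple <- w + 3 * sin(2 * pi * 5 * t)
  expect_gt(normalized_angular_jerk_score(ripple, 100),
            normalized_angular_jerk_score(w, 100))
  expect_error(normalized_angular_jerk_score(sin(2 * pi * t), 100),
               class = "itug_amplitude_error")
})

test_that("turn kinematics follow closed forms and ground truth", {
  fs <- 1000   # fine grid so the discrete max is close to the peak
  tau <- seq(0, 1, by = 1 / fs)
  pulse <- 120 * sin(pi * tau)
  tk <- turn_kinematics(pulse, fs)
  expect_equal(unname(tk["peak"]), 120, tolerance = 0.01)
  expect_equal(unname(tk["mean"]), 2 * 120 / pi, tolerance = 0.01 * 120)
  tk2 <- turn_kinematics(rep(-7, 100), 100)
  expect_equal(unname(tk2), c(7, 7))

  # generator ground truth via the full extractor
  tr <- simulate_trial(demo_profile(), seed = 17)
  seg <- segment_trial(tr$recording)
  fv <- extract_features(tr$recording, seg)
  expect_equal(unname(fv["turn_peak_vel_ft"]),
               unname(tr$truth$turn_peak["ft"]), tolerance = 0.03 * 160)
})

test_that("step detection counts analytic peaks and ignores flat signals", {
  fs <- 100
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  steps <- detect_steps(sin(2 * pi * 2 * t), fs)
  expect_length(steps, 6L)
  expect_length(detect_steps(rep(0, 300), fs), 0L)
  expect_error(detect_steps(rep(0, 20), fs), class = "itug_argument_error")
})

test_that("step counts recover generator ground truth on most trials", {
  co <- simulate_cohort(20, 10, seed = 31)
  hits <- 0; n_tr <- 40
  for (i in seq_len(n_tr)) {
    pr <- co$profiles[(i - 1) %% 30 + 1, ]
    tr <- simulate_trial(pr, seed = 400 + i)
    seg <- segment_trial(tr$recording)
    fv <- extract_features(tr$recording, seg)
    truth_w <- length(tr$truth$steps$w1) + length(tr$truth$steps$w2)
    if (abs(fv[["steps_w"]] - truth_w) <= 1) hits <- hits + 1
  }
  expect_gte(hits / n_tr, 0.9)
})

test_that("gait metrics are arithmetic on the nominal 6 m round trip", {
  g <- gait_metrics(2, 2, 8)
  expect_equal(unname(g), c(1.5, 0.75, 2.0))
  expect_error(gait_metrics(0, 2, 8), class = "itug_argument_error")
  expect_error(gait_metrics(2, 2, 0), class = "itug_gait_error")

  tr <- simulate_trial(demo_profile(), seed = 19)
  seg <- segment_trial(tr$recording)
  fv <- extract_features(tr$recording, seg)
  expect_equal(unname(fv["gait_speed"]), tr$truth$params$gait_speed,
               tolerance = 0.05 * tr$truth$params$gait_speed)
})

test_that("step regularity separates periodic from random signals", {
  fs <- 100
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  periodic <- cos(2 * pi * 2 * t)
  expect_equal(step_regularity(periodic, fs), 100, tolerance = 2)

  # white-noise null: near zero on average (Monte-Carlo median)
  set.seed(7)
  nulls <- replicate(40, step_regularity(rnorm(400), fs))
  expect_lt(median(abs(nulls)), 15)

  noisy <- periodic + rnorm(length(t), 0, 1)
  r_noisy <- step_regularity(noisy, fs)
  expect_gt(r_noisy, median(abs(nulls)))
  expect_lt(r_noisy, 99)
  expect_error(step_regularity(periodic[1:60], fs),
               class = "itug_gait_error")
})

test_that("the extractor fills all 78 catalogue features consistently", {
  man <- feature_manifest()
  expect_equal(nrow(man), 78L)
  expect_false(anyDuplicated(man$name) > 0)
  expect_true("Gait speed [m/s]" %in% man$label)

  tr <- simulate_trial(demo_profile(), seed = 23)
  seg <- segment_trial(tr$recording)
  fv <- extract_features(tr$recording, seg)
  expect_equal(length(fv), 78L)
  expect_identical(names(fv), man$name)
  expect_equal(sum(is.na(fv)), 0L)

  # definitions: total duration and step additivity
  expect_equal(unname(fv["dur_total"]),
               seg$total[2] - seg$total[1], tolerance = 1e-9)
  expect_equal(unname(fv["steps_total"]),
               unname(fv["steps_w"] + fv["steps_ft"] + fv["steps_tts"]))
  # gait speed is 6 m over the summed walking legs by construction
  expect_equal(unname(fv["gait_speed"]),
               6 / unname(fv["dur_w1"] + fv["dur_w2"]), tolerance = 1e-9)
  # walk duration matches ground truth
  b <- tr$truth$boundaries
  truth_w <- (b["ft_start"] - b["stw_end"]) +
    (b["tts_turn_start"] - b["ft_end"])
  expect_equal(unname(fv["dur_w"]), unname(truth_w), tolerance = 0.2)
})

test_that("feature averaging is a per-feature mean that tolerates gaps", {
  v <- stats::setNames(as.numeric(1:5), paste0("f", 1:5))
  expect_equal(average_features(list(v, v, v, v, v)), v)
  vs <- lapply(1:5, function(k) stats::setNames(rep(k, 3), c("a", "b", "c")))
  expect_equal(unname(average_features(vs)), rep(3, 3))
  vs[[3]]["b"] <- NA
  expect_equal(unname(average_features(vs)["b"]), mean(c(1, 2, 4, 5)))
  all_na <- lapply(1:2, function(k) c(a = NA_real_))
  expect_true(is.nan(average_features(all_na)[["a"]]))
  bad <- list(c(a = 1), c(b = 1))
  expect_error(average_features(bad), class = "itug_schema_error")
})
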