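# Session splitting, turn/transition detection and phase segmentation.

test_that("split_repetitions needs activity and finds single trials", {
  quiet <- imu_recording(seq(0, 10, by = 0.01),
                         matrix(0, 1001, 3), matrix(0, 1001, 3),
                         rate = 100, axes = c("AP", "ML", "V"))
  expect_error(split_repetitions(quiet), class = "itug_no_activity")

  tr <- simulate_trial(demo_profile(), seed = 1)
  reps <- split_repetitions(tr$recording)
  expect_length(reps, 1L)
})

test_that("detect_turns finds pulses with accurate extent and angle", {
  n <- 801
  t <- (seq_len(n) - 1) / 100
  w <- rep(0, n)
  # one smooth 180 deg half-sine pulse over 2 s, centred at t = 4
  on <- t >= 3 & t < 5
  w[on] <- 90 * pi / 2 * sin(pi * (t[on] - 3) / 2)
  rec <- imu_recording(t, matrix(0, n, 3), cbind(0, 0, w),
                       rate = 100, axes = c("AP", "ML", "V"))
  turns <- detect_turns(rec)
  expect_equal(nrow(turns), 1L)
  expect_equal(turns$start, 3, tolerance = 0.1)
  expect_equal(turns$end, 5, tolerance = 0.1)
  expect_equal(turns$angle, 180, tolerance = 5)
  expect_equal(turns$peak, 90 * pi / 2, tolerance = 0.05 * 90 * pi / 2)

  # zero signal: no turns
  rec0 <- imu_recording(t, matrix(0, n, 3), matrix(0, n, 3),
                        rate = 100, axes = c("AP", "ML", "V"))
  expect_equal(nrow(detect_turns(rec0)), 0L)

  # two pulses separated by walking oscillation come back in order
  w2 <- w
  on2 <- t >= 6.5 & t < 7.5
  w2[on2] <- -150 * sin(pi * (t[on2] - 6.5))
  mid <- t >= 5 & t < 6.5
  w2[mid] <- 8 * cos(2 * pi * 2 * t[mid])
  rec2 <- imu_recording(t, matrix(0, n, 3), cbind(0, 0, w2),
                        rate = 100, axes = c("AP", "ML", "V"))
  turns2 <- detect_turns(rec2)
  expect_equal(nrow(turns2), 2L)
  expect_true(turns2$start[1] < turns2$start[2])
  expect_lt(turns2$angle[2], 0)

  # a constant bias below the detrending level does not change the angle
  recb <- imu_recording(t, matrix(0, n, 3), cbind(0, 0, w + 1),
                        rate = 100, axes = c("AP", "ML", "V"))
  expect_equal(detect_turns(recb)$angle, turns$angle, tolerance = 2)
})

test_that("detect_transitions finds onset and sit-end near ground truth", {
  tr <- simulate_trial(demo_profile(), seed = 5)
  trans <- detect_transitions(tr$recording)
  b <- tr$truth$boundaries
  expect_equal(trans$onset, unname(b["stw_start"]), tolerance = 0.15)
  expect_equal(trans$sit_end, unname(b["sit_end"]), tolerance = 0.20)

  # no quiet lead-in: start the recording inside the movement
  act <- crop_recording(tr$recording, b["stw_start"] + 0.3, b["sit_end"])
  expect_error(detect_transitions(act), class = "itug_baseline_error")
})

test_that("time reversal swaps the roles of onset and sit-end", {
  tr <- simulate_trial(demo_profile(), seed = 8)
  rec <- tr$recording
  n <- length(rec$time)
  rev_rec <- imu_recording(rec$time, rec$acc[n:1, ], rec$gyro[n:1, ],
                           rate = rec$rate, axes = rec$axes)
  fwd <- detect_transitions(rec)
  bwd <- detect_transitions(rev_rec)
  total_t <- rec$time[n]
  expect_equal(bwd$onset, total_t - fwd$sit_end, tolerance = 0.25)
  expect_equal(bwd$sit_end, total_t - fwd$onset, tolerance = 0.25)
})

test_that("segment_trial recovers the phase structure", {
  tr <- simulate_trial(demo_profile(), seed = 11)
  seg <- segment_trial(tr$recording)
  expect_s3_class(seg, "trial_segmentation")
  p <- seg$phases
  expect_equal(p$phase, c("StW", "W1", "FT", "W2", "TtS"))
  expect_true(all(diff(p$start) > 0))
  expect_true(all(p$end >= p$start))
  # contiguity and sub-interval containment
  expect_equal(p$start[-1], p$end[-5])
  expect_gte(seg$tts_turn[1], p$start[5] - 1e-9)
  expect_lte(seg$tts_sit[2], p$end[5] + 1e-9)
  b <- tr$truth$boundaries
  expect_equal(p$start[1], unname(b["stw_start"]), tolerance = 0.15)
  expect_equal(seg$total[2], unname(b["sit_end"]), tolerance = 0.2)
})

test_that("phase order always holds on noiseless trials", {
  co <- simulate_cohort(10, 5, seed = 21)
  for (i in seq_len(nrow(co$profiles))) {
    tr <- simulate_trial(co$profiles[i, ], seed = 50 + i,
                         noise_acc = 0, noise_gyro = 0)
    seg <- segment_trial(tr$recording)
    expect_true(!is.unsorted(seg$phases$start))
    expect_equal(diff(seg$total),
                 unname(tr$truth$boundaries["sit_end"] -
                          tr$truth$boundaries["stw_start"]),
                 tolerance = 0.2)
  }
})

test_that("a third spurious turn makes segmentation fail with diagnostics", {
  tr <- simulate_trial(demo_profile(), seed = 13)
  rec <- tr$recording
  # inject a spurious >90 deg turn into the trailing quiet sitting
  t <- rec$time
  sit_end <- tr$truth$boundaries["sit_end"]
  on <- t >= sit_end + 0.5 & t < sit_end + 1.5
  rec$gyro[on, "V"] <- rec$gyro[on, "V"] + 160 * sin(pi * (t[on] - sit_end - 0.5))
  err <- tryCatch(segment_trial(rec), error = identity)
  expect_s3_class(err, "itug_segmentation_error")
  expect_match(conditionMessage(err), "found 3")
})
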