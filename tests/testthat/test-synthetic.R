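# Cohort, trial and feature-table generators.

test_that("simulate_cohort handles empty cohorts and is deterministic", {
  co <- simulate_cohort(0, 0, seed = 1)
  expect_equal(nrow(co$profiles), 0L)
  expect_equal(nrow(co$clinical), 0L)

  a <- simulate_cohort(20, 10, seed = 42)
  b <- simulate_cohort(20, 10, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(20, 10, seed = 43)))
  expect_error(simulate_cohort(-1, 0), class = "itug_argument_error")
})

test_that("generated scores respect their scale bounds", {
  co <- simulate_cohort(300, 300, seed = 5)
  expect_true(all(co$cbms$cbms >= 0 & co$cbms$cbms <= 96))
  cl <- co$clinical
  expect_true(all(cl$sppb >= 0 & cl$sppb <= 12))
  expect_true(all(cl$lbs8 >= 1 & cl$lbs8 <= 8))
  expect_true(all(cl$fes_i_short >= 7 & cl$fes_i_short <= 28))
  expect_true(all(cl$gait_habitual >= 0.2 & cl$gait_habitual <= 2.5))
  expect_true(all(co$profiles$gait_speed > 0.2 &
                    co$profiles$gait_speed < 2.5))
  expect_true(all(cl$sppb == round(cl$sppb)))
})

test_that("latent ability links monotonically to CBMS and kinematics", {
  co <- simulate_cohort(400, 200, seed = 3)
  expect_gt(cor(co$profiles$theta, co$cbms$cbms, method = "spearman"), 0.9)
  expect_gt(cor(co$profiles$theta, co$profiles$gait_speed,
                method = "spearman"), 0.8)
  expect_lt(cor(co$profiles$theta, co$clinical$tug_s,
                method = "spearman"), -0.6)
})

test_that("noiseless trials integrate to the constructed turn angle", {
  tr <- simulate_trial(demo_profile(), seed = 2, noise_acc = 0, noise_gyro = 0)
  b <- tr$truth$boundaries
  idx <- tr$recording$time >= b["ft_start"] & tr$recording$time < b["ft_end"]
  angle <- pracma::trapz(tr$recording$time[idx], tr$recording$gyro[idx, "V"])
  expect_equal(angle, 180, tolerance = 1 / 180)
  # second turn is opposite in sign
  idx2 <- tr$recording$time >= b["tts_turn_start"] &
    tr$recording$time < b["tts_turn_end"]
  angle2 <- pracma::trapz(tr$recording$time[idx2],
                          tr$recording$gyro[idx2, "V"])
  expect_equal(angle2, -180, tolerance = 1 / 180)
})

test_that("walk-out footfalls match the peaks of the generated signal", {
  tr <- simulate_trial(demo_profile(), seed = 4, noise_acc = 0, noise_gyro = 0)
  b <- tr$truth$boundaries
  d_w1 <- b["ft_start"] - b["stw_end"]
  cad <- tr$truth$params$cadence
  expect_equal(length(tr$truth$steps$w1), floor(unname(d_w1) * cad - 1e-9) + 1)
  # count analytic maxima of the vertical oscillation over the leg
  idx <- which(tr$recording$time >= b["stw_end"] &
                 tr$recording$time < b["ft_start"])
  v <- tr$recording$acc[idx, "V"]
  n_peaks <- sum(diff(sign(diff(v))) < 0)
  expect_lte(abs(n_peaks - length(tr$truth$steps$w1)), 1)
  # chair-to-cone distance is fixed at 3 m: leg duration x speed = 3
  expect_equal(unname(d_w1) * tr$truth$params$gait_speed, 3,
               tolerance = 0.02)
})

test_that("sessions concatenate five trials with 30 s rests", {
  pr <- demo_profile()
  ses <- simulate_session(pr, seed = 6)
  expect_length(ses$truth, 5L)
  one <- simulate_trial(pr, seed = 1)
  dur <- max(ses$recording$time)
  expect_equal(dur, 5 * max(one$recording$time) + 4 * 30, tolerance = 10)
  reps <- split_repetitions(ses$recording)
  expect_length(reps, 5L)
  # each repetition window contains its ground-truth trial interval
  for (r in seq_len(5)) {
    off <- attr(reps[[r]], "offset")
    b <- ses$truth[[r]]$boundaries
    expect_lte(off, b["stw_start"])
    expect_gte(off + max(reps[[r]]$time), b["sit_end"])
  }
})

test_that("repetition-to-repetition variation is below between-subject variation", {
  co <- simulate_cohort(12, 6, seed = 9)
  speeds <- sapply(seq_len(nrow(co$profiles)), function(i) {
    sapply(1:3, function(r)
      simulate_trial(co$profiles[i, ], repetition = r,
                     seed = 100 * i + r)$truth$params$gait_speed)
  })  # 3 x n matrix
  within_sd <- mean(apply(speeds, 2, sd))
  between_sd <- sd(colMeans(speeds))
  expect_lt(within_sd, between_sd)
})

test_that("latent feature tables have the advertised structure", {
  # noiseless single factor: one PLS component explains everything
  tab <- simulate_feature_table(30, 10, k_true = 1, noise_sd = 0,
                                x_noise_sd = 0, seed = 1)
  f <- fit_pls1(tab, 1)
  expect_equal(sum(explained_variation(f)), 1, tolerance = 1e-8)

  # joint row permutation leaves the fitted R^2 unchanged
  tab2 <- simulate_feature_table(40, 12, k_true = 3, seed = 2)
  f2 <- fit_pls1(tab2, 3)
  set.seed(11)
  perm <- sample(40)
  f2p <- fit_pls1(feature_table(tab2$X[perm, ], tab2$y[perm]), 3)
  expect_equal(sum(explained_variation(f2)), sum(explained_variation(f2p)),
               tolerance = 1e-8)

  expect_error(simulate_feature_table(10, 5, k_true = 6),
               class = "itug_argument_error")

  # determinism
  expect_identical(simulate_feature_table(20, 8, seed = 3),
                   simulate_feature_table(20, 8, seed = 3))

  # the generating r2 solves the noise level
  tab3 <- simulate_feature_table(500, 20, k_true = 3, r2 = 0.85, seed = 4)
  expect_equal(attr(tab3, "truth")$r2, 0.85, tolerance = 1e-12)
})
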