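# Shared fixtures built in code at test time.

# a small uniform recording with known analytic channels
make_recording <- function(dur = 2, fs = 100, f = 1) {
  t <- seq(0, dur, by = 1 / fs)
  acc <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 9.81 + 0 * t)
  gyro <- cbind(0 * t, 0 * t, 10 * sin(2 * pi * f * t))
  imu_recording(t, acc, gyro, rate = fs, axes = c("AP", "ML", "V"))
}

# minimum-jerk acceleration samples for unit displacement over duration T
minjerk_acc_samples <- function(T = 2, fs = 100, A = 1) {
  tau <- seq(0, 1, by = 1 / (T * fs))
  A / T^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
}

# minimum-jerk angular velocity samples for `angle` degrees over T seconds
minjerk_omega_samples <- function(T = 2, fs = 100, angle = 180) {
  tau <- seq(0, 1, by = 1 / (T * fs))
  angle / T * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}

# one community-like profile for signal-level tests
demo_profile <- function() {
  data.frame(id = "S001", cohort = "community", theta = 0.5,
             gait_speed = 1.25, cadence = 2.0, turn_peak = 160,
             stw_duration = 1.2, sit_duration = 1.4, step_amp = 1.6)
}
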