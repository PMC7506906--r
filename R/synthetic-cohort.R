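# Synthetic cohort generator: latent ability, CBMS, clinical tests and
# per-subject kinematic parameters for the trial signal generator.

#' Calibration targets for the synthetic cohorts
#'
#' Per-variable calibration of the two simulated cohorts: 40
#' community-dwelling seniors and 20 geriatric outpatients is the study
#' design the generator emulates. For each variable the table holds the
#' target mean and SD per cohort, the admissible range of the scale, the
#' correlation `rho` linking the variable to the latent ability factor
#' (signed: negative for variables that worsen, i.e. increase, as ability
#' declines is positive rho; e.g. TUG time has negative rho), and whether
#' the scale is integer-valued.
#'
#' Bounded scales are generated by clamping a Gaussian to the scale range;
#' the pre-clamp mean and SD are solved numerically (moment matching of the
#' clamped distribution) so that the post-clamp sample moments reproduce
#' the targets, which matters for strongly censored scales such as the
#' outpatient CBMS or the community SPPB.
#'
#' @return A data.frame with one row per calibrated variable.
#' @export
cohort_reference_table <- function() {
  df <- read.csv(text = "
variable,mean_com,sd_com,mean_out,sd_out,lower,upper,rho,integer
age,71.8,7.3,78.9,5.9,55,95,-0.25,1
education,14.6,3.7,11.5,4.3,5,25,0.20,1
height,169.5,9.6,165.9,11.1,140,200,0.10,0
weight,72.0,12.6,75.5,16.9,40,130,0.00,0
cbms,66.7,18.3,15.0,17.2,0,96,0.95,1
tug_s,8.3,1.2,13.9,4.0,3,60,-0.80,0
sppb,11.7,0.9,9.0,2.4,0,12,0.75,1
cst30,15.3,2.9,8.8,3.3,0,40,0.75,1
lbs8,5.4,1.5,4.3,1.4,1,8,0.70,1
gait_habitual,1.36,0.20,0.88,0.21,0.2,2.5,0.80,0
gait_fast,1.83,0.27,1.18,0.30,0.25,3.5,0.80,0
fes_i_short,8.1,1.5,10.7,4.0,7,28,-0.70,1
", stringsAsFactors = FALSE)
  df$integer <- df$integer == 1
  df
}

# Mean and SD of clamp(N(mu, sigma), a, b).
clamped_normal_moments <- function(mu, sigma, a, b) {
  za <- (a - mu) / sigma; zb <- (b - mu) / sigma
  Pa <- stats::pnorm(za); Pb <- stats::pnorm(zb); dP <- Pb - Pa
  fa <- stats::dnorm(za); fb <- stats::dnorm(zb)
  m1 <- a * Pa + b * (1 - Pb) + mu * dP + sigma * (fa - fb)
  m2 <- a^2 * Pa + b^2 * (1 - Pb) + mu^2 * dP + 2 * mu * sigma * (fa - fb) +
    sigma^2 * (dP + ifelse(is.finite(za), za * fa, 0) -
                 ifelse(is.finite(zb), zb * fb, 0))
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Pre-clamp (mu, sigma) whose clamped distribution has the target moments.
solve_preclamp <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    mm <- clamped_normal_moments(p[1], exp(p[2]), a, b)
    (mm[1] - target_mean)^2 / target_sd^2 + (mm[2] - target_sd)^2 / target_sd^2
  }
  o <- stats::optim(c(target_mean, log(target_sd)), obj,
                    method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  c(mu = o$par[1], sigma = exp(o$par[2]))
}

# cache the solved pre-clamp parameters (they depend only on the table)
.preclamp_cache <- new.env(parent = emptyenv())
preclamp_params <- function() {
  if (!is.null(.preclamp_cache$p)) return(.preclamp_cache$p)
  ref <- cohort_reference_table()
  p <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    com <- solve_preclamp(ref$mean_com[i], ref$sd_com[i], ref$lower[i], ref$upper[i])
    out <- solve_preclamp(ref$mean_out[i], ref$sd_out[i], ref$lower[i], ref$upper[i])
    data.frame(variable = ref$variable[i],
               mu_com = com[1], sigma_com = com[2],
               mu_out = out[1], sigma_out = out[2])
  }))
  .preclamp_cache$p <- p
  p
}

# Latent-ability distribution per cohort on a common standardized scale.
.theta_pars <- list(community = c(mean = 0.5, sd = 0.7),
                    outpatient = c(mean = -1.0, sd = 0.9))

#' Simulate a two-cohort study population
#'
#' Draws a latent ability factor `theta` per subject (cohort-specific
#' Gaussians on a common standardized scale) and maps it monotonically to
#' the CBMS response, every clinical test score and the kinematic
#' parameters that drive the trial signal generator. Each variable receives
#' test-specific Gaussian noise and is clamped (and, for integer scales,
#' rounded) to its admissible range; the calibration in
#' [cohort_reference_table()] makes per-cohort sample means and SDs
#' reproduce the study-population characteristics.
#'
#' Besides the dominant ability factor, each subject carries two minor
#' latent factors: a turn-specific factor (feeding the turning velocity)
#' and a transition-specific factor (feeding the sit-to-stand and
#' sit-down durations). Both contribute a small share of the CBMS
#' response but are invisible to the global clinical tests, so balance
#' variance beyond overall ability is only recoverable from the movement
#' features — the structure a multi-component regression is meant to
#' exploit.
#'
#' @param n_community,n_outpatient cohort sizes (the emulated study used
#'   40 and 20).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A list with class `itug_cohort`:
#' \describe{
#'   \item{profiles}{data.frame of subject id, cohort, `theta` and the
#'     kinematic parameters consumed by [simulate_trial()]: `gait_speed`
#'     (m/s), `cadence` (steps/s), `turn_peak` (deg/s), `stw_duration`,
#'     `sit_duration` (s), `step_amp` (m/s^2), plus descriptives.}
#'   \item{clinical}{data.frame of descriptives and clinical test scores.}
#'   \item{cbms}{data.frame of subject id and CBMS total score (0-96).}
#'   \item{truth}{generating parameters: per-subject theta and the
#'     latent-to-score links used.}
#' }
#' @export
simulate_cohort <- function(n_community = 40, n_outpatient = 20, seed = 1) {
  if (n_community < 0 || n_outpatient < 0)
    stop_itug("itug_argument_error", "cohort sizes must be non-negative")
  n <- n_community + n_outpatient
  ref <- cohort_reference_table()
  pre <- preclamp_params()
  cohort <- rep(c("community", "outpatient"), c(n_community, n_outpatient))
  out <- with_seed(seed, {
    z <- stats::rnorm(n)        # within-cohort standardized ability
    t_turn <- stats::rnorm(n)   # minor turn-specific factor
    t_trans <- stats::rnorm(n)  # minor transition-specific factor
    tp <- do.call(rbind, .theta_pars)[cohort, , drop = FALSE]
    theta <- tp[, "mean"] + tp[, "sd"] * z
    # CBMS responds to overall ability plus the minor factors; clinical
    # tests see overall ability only
    z_cbms <- (z + 0.30 * t_turn + 0.25 * t_trans) /
      sqrt(1 + 0.30^2 + 0.25^2)
    clin <- data.frame(id = sprintf("S%03d", seq_len(n)), cohort = cohort,
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ref))) {
      v <- ref$variable[i]
      mu <- ifelse(cohort == "community", pre$mu_com[i], pre$mu_out[i])
      sg <- ifelse(cohort == "community", pre$sigma_com[i], pre$sigma_out[i])
      rho <- ref$rho[i]
      zz <- if (v == "cbms") z_cbms else z
      x <- mu + sg * (rho * zz + sqrt(1 - rho^2) * stats::rnorm(n))
      x <- pmin(pmax(x, ref$lower[i]), ref$upper[i])
      if (ref$integer[i]) x <- round(x)
      clin[[v]] <- x
    }
    p_female <- ifelse(cohort == "community", 23 / 40, 9 / 20)
    clin$sex <- ifelse(stats::runif(n) < p_female, "F", "M")
    clin$bmi <- clin$weight / (clin$height / 100)^2
    kin <- function(latent, base, slope, noise, lo, hi)
      pmin(pmax(base + slope * (latent + noise * stats::rnorm(n)), lo), hi)
    th_turn <- theta + 0.5 * t_turn    # turning draws on its own factor
    th_trans <- theta + 0.4 * t_trans  # transitions likewise
    profiles <- data.frame(
      id = clin$id, cohort = cohort, theta = theta,
      turn_factor = t_turn, trans_factor = t_trans,
      gait_speed = kin(theta, 1.15, 0.35, 0.12, 0.35, 2.30),
      cadence = kin(theta, 1.90, 0.12, 0.15, 1.30, 2.60),
      turn_peak = kin(th_turn, 150, 40, 0.15, 60, 280),
      stw_duration = kin(th_trans, 1.30, -0.22, 0.15, 0.70, 3.00),
      sit_duration = kin(th_trans, 1.50, -0.20, 0.15, 0.80, 3.20),
      step_amp = kin(theta, 1.50, 0.30, 0.20, 0.60, 3.00),
      age = clin$age, education = clin$education, sex = clin$sex,
      height = clin$height, weight = clin$weight, bmi = clin$bmi,
      stringsAsFactors = FALSE)
    cbms <- data.frame(id = clin$id, cbms = clin$cbms)
    clin$cbms <- NULL
    # reorder clinical columns: descriptives then tests
    clin <- clin[, c("id", "cohort", "age", "education", "sex", "height",
                     "weight", "bmi", "tug_s", "gait_habitual", "gait_fast",
                     "sppb", "cst30", "lbs8", "fes_i_short")]
    list(profiles = profiles, clinical = clin, cbms = cbms,
         truth = list(theta = stats::setNames(theta, clin$id),
                      turn_factor = t_turn, trans_factor = t_trans,
                      reference = ref, seed = seed))
  })
  structure(out, class = "itug_cohort")
}

#' @export
print.itug_cohort <- function(x, ...) {
  cat(sprintf("<itug_cohort> %d community, %d outpatient subjects\n",
              sum(x$profiles$cohort == "community"),
              sum(x$profiles$cohort == "outpatient")))
  invisible(x)
}
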