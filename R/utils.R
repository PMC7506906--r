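# Internal numeric helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive n reproducible sub-seeds (< 2^31) from one master seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stop_itug <- function(class, msg, ...) {
  stop(structure(class = c(class, "itug_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Zero-phase Butterworth low-pass with reflection padding so short pulses
# near the record edges are not distorted by filter start-up transients.
lowpass <- function(x, cutoff, fs, order = 4) {
  n <- length(x)
  if (n < 8 || cutoff >= fs / 2) return(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- min(n - 1L, as.integer(round(fs)))
  xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
          2 * x[n] - rev(x[n - seq_len(pad)]))
  yp <- signal::filtfilt(bf, xp)
  yp[pad + seq_len(n)]
}

bandpass <- function(x, low, high, fs, order = 2) {
  n <- length(x)
  if (n < 8 || high >= fs / 2) return(x - mean(x))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  pad <- min(n - 1L, as.integer(round(fs)))
  xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
          2 * x[n] - rev(x[n - seq_len(pad)]))
  yp <- signal::filtfilt(bf, xp)
  yp[pad + seq_len(n)]
}

# Centered moving standard deviation; edges take the nearest interior value.
moving_sd <- function(x, width) {
  width <- max(3L, as.integer(width))
  k <- rep(1 / width, width)
  m1 <- stats::filter(x, k, sides = 2)
  m2 <- stats::filter(x^2, k, sides = 2)
  s <- sqrt(pmax(as.numeric(m2) - as.numeric(m1)^2, 0))
  idx <- which(!is.na(s))
  if (length(idx) == 0) return(rep(stats::sd(x), length(x)))
  s[seq_len(idx[1] - 1L)] <- s[idx[1]]
  s[seq(idx[length(idx)] + 1L, length.out = length(x) - idx[length(idx)])] <-
    s[idx[length(idx)]]
  s
}

# Contiguous runs of TRUE as a two-column matrix of start/end indices.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
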