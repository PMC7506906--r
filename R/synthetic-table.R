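#' Simulate a latent-factor feature table
#'
#' Direct test harness for the regression and cross-validation machinery,
#' bypassing signal synthesis. Generates `X = T S P' + E` with `k_true`
#' orthogonal latent score vectors (columns of `T`, unit variance),
#' component strengths `S = diag(strength)` and Gaussian feature noise `E`,
#' and a response `Y = T c + e`. The population explained variance of `Y`
#' is `sum(c^2) / (sum(c^2) + noise_sd^2)`.
#'
#' By default the response loadings `c` are anti-ordered relative to the
#' predictor-space strengths: the factor dominating the predictor
#' variance contributes least to the response. This mismatch makes every
#' one of the `k_true` components genuinely necessary — a single blended
#' direction cannot shortcut the response, so each extracted component
#' carries a material share of response variance (population shares
#' roughly 0.6 / 0.25 / 0.12 at the `k_true = 3` defaults) and
#' cross-validated RMSEP bottoms out at `k_true` components. With
#' loadings proportional to strengths one blended component would explain
#' almost everything.
#'
#' @param n,m numbers of rows (subjects) and feature columns.
#' @param k_true number of latent components (must be `<= min(n, m)`).
#' @param noise_sd SD of the response noise `e`. Ignored when `r2` is
#'   given, in which case it is solved so the generating explained
#'   variance equals `r2`.
#' @param x_noise_sd SD of the feature noise `E`.
#' @param strength latent component strengths in predictor space
#'   (recycled/truncated to `k_true`); default log-spaced from 5 down
#'   to 1.
#' @param y_loadings response loadings `c`; default log-spaced from 1.2
#'   up to 2.5 (anti-ordered to `strength`).
#' @param r2 optional target generating R^2 in (0, 1].
#' @param seed integer seed.
#' @return A [feature_table()] whose `truth` attribute stores `scores`,
#'   `loadings`, `strength`, `noise_sd` and the generating `r2`.
#' @export
simulate_feature_table <- function(n, m, k_true = 3, noise_sd = NULL,
                                   x_noise_sd = 1, strength = NULL,
                                   y_loadings = NULL, r2 = NULL, seed = 1) {
  if (k_true > min(n, m))
    stop_itug("itug_argument_error",
              "k_true (%d) must not exceed min(n, m) = %d", k_true, min(n, m))
  if (is.null(strength))
    strength <- if (k_true == 1) 5 else
      exp(seq(log(5), log(1), length.out = k_true))
  strength <- rep_len(strength, k_true)
  cvec <- if (is.null(y_loadings)) {
    if (k_true == 1) 2.5 else
      exp(seq(log(1.2), log(2.5), length.out = k_true))
  } else rep_len(y_loadings, k_true)
  sig2 <- sum(cvec^2)
  if (!is.null(r2)) {
    if (r2 <= 0 || r2 > 1)
      stop_itug("itug_argument_error", "r2 must be in (0, 1]")
    noise_sd <- sqrt(sig2 * (1 - r2) / r2)
  } else if (is.null(noise_sd)) {
    noise_sd <- sqrt(sig2 * 0.15 / 0.85)
  }
  with_seed(seed, {
    Tm <- qr.Q(qr(matrix(stats::rnorm(n * k_true), n, k_true)))
    Tm <- sweep(Tm, 2, apply(Tm, 2, stats::sd), `/`)   # unit-variance scores
    P <- matrix(stats::rnorm(m * k_true), m, k_true)
    X <- Tm %*% diag(strength, k_true) %*% t(P) +
      matrix(stats::rnorm(n * m, 0, x_noise_sd), n, m)
    y <- drop(Tm %*% cvec) + stats::rnorm(n, 0, noise_sd)
    colnames(X) <- sprintf("f%03d", seq_len(m))
    tab <- feature_table(X, y, ids = sprintf("S%03d", seq_len(n)))
    attr(tab, "truth") <- list(scores = Tm, loadings = P,
                               strength = strength, c = cvec,
                               noise_sd = noise_sd, x_noise_sd = x_noise_sd,
                               r2 = sig2 / (sig2 + noise_sd^2))
    tab
  })
}
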