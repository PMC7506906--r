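# Monte-Carlo cross-validation with embedded univariate feature screening,
# RMSEP-based component choice, aggregated VIP / explained variation, and
# paired between-model comparison of prediction error.

#' Cross-validation configuration
#'
#' @param n_iter number of Monte-Carlo iterations (default 100).
#' @param n_folds number of partitions per iteration (default 6; five
#'   train, one test).
#' @param alpha significance level of the univariate correlation screen
#'   applied to the training split of every iteration.
#' @param a_max maximum number of PLS components evaluated.
#' @param seed master seed; per-iteration substreams are derived from it.
#' @param selection_threshold features selected in more than this fraction
#'   of iterations enter the final model.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_iter = 100, n_folds = 6, alpha = 0.05, a_max = 10,
                      seed = 1, selection_threshold = 0.5) {
  if (n_folds < 2) stop_itug("itug_argument_error", "n_folds must be >= 2")
  if (alpha <= 0 || alpha >= 1)
    stop_itug("itug_argument_error", "alpha must be in (0, 1)")
  if (n_iter < 1) stop_itug("itug_argument_error", "n_iter must be >= 1")
  structure(as.list(environment()), class = "cv_config")
}

#' Screen features by correlation with the response
#'
#' For each feature, the Pearson correlation with `y` and its two-sided
#' t-test p-value; features with `p < alpha` are selected. Zero-variance
#' features are excluded (recorded, not an error). Run inside every
#' cross-validation iteration on the training rows only, so the screen can
#' never see the test data.
#'
#' @param X predictor matrix (training rows).
#' @param y response (training rows).
#' @param alpha significance level.
#' @return data.frame with `name`, `r`, `p`, `selected`.
#' @export
select_features <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4)
    stop_itug("itug_argument_error", "need at least 4 training rows")
  sx <- apply(X, 2, stats::sd)
  ok <- sx > 0 & stats::sd(y) > 0
  r <- rep(NA_real_, ncol(X))
  r[ok] <- drop(stats::cor(X[, ok, drop = FALSE], y))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) > 1 - 1e-12] <- 0
  data.frame(name = colnames(X), r = r, p = p,
             selected = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Choose the PLS component count from an RMSEP curve
#'
#' One-standard-error parsimony rule on the Monte-Carlo RMSEP curve: the
#' candidates are the component counts whose mean RMSEP lies within one
#' standard error of the minimum (the SD at the minimizing count divided
#' by `sqrt(n_iter)`), i.e. counts statistically indistinguishable from
#' the minimum mean; among candidates the smallest count wins. This
#' reproduces the convention of retaining the smaller model when a larger
#' one is only insignificantly better (e.g. mean RMSEP 11.81 at three
#' components versus 11.79 at four retains three).
#'
#' @param rmsep_mean,rmsep_sd equal-length curves over component counts
#'   `1..length(rmsep_mean)` (SD taken across Monte-Carlo iterations).
#' @param n_iter number of iterations behind the curve; the tolerance is
#'   `rmsep_sd / sqrt(n_iter)`. The default 1 uses the raw SD.
#' @return The chosen component count.
#' @export
choose_components <- function(rmsep_mean, rmsep_sd, n_iter = 1) {
  if (length(rmsep_mean) != length(rmsep_sd) || length(rmsep_mean) < 1)
    stop_itug("itug_argument_error", "curves must have equal length >= 1")
  ok <- !is.na(rmsep_mean)
  if (!any(ok))
    stop_itug("itug_argument_error", "RMSEP curve is entirely missing")
  i0 <- which.min(replace(rmsep_mean, !ok, Inf))
  tol <- if (is.na(rmsep_sd[i0])) 0 else rmsep_sd[i0] / sqrt(n_iter)
  cand <- which(ok & rmsep_mean <= rmsep_mean[i0] + tol)
  # parsimony: the smallest count that is indistinguishable from the best
  min(cand)
}

#' Percentile confidence interval
#'
#' @param samples numeric vector (>= 2 values).
#' @param level confidence level (default 0.95).
#' @return Named vector `c(lo, hi)` of linear-interpolation quantiles at
#'   `(1 - level)/2` and `1 - (1 - level)/2`.
#' @export
confidence_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2)
    stop_itug("itug_argument_error", "need at least 2 samples")
  q <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Monte-Carlo cross-validation of a PLS1 model
#'
#' Each iteration randomly repartitions the rows into `n_folds` near-equal
#' sets, trains on all but the last set, screens features on the training
#' rows only ([select_features()]), fits PLS1 up to `a_max` components and
#' records the held-out RMSEP for every component count. Aggregates across
#' iterations give the RMSEP curve (mean and SD per component count), the
#' per-feature selection frequency, the chosen component count
#' ([choose_components()]), the final feature set (selection frequency
#' above the configured threshold), a final model refitted on all rows
#' restricted to that set, its VIP scores, and the per-component explained
#' variation of the training fits with percentile confidence intervals.
#'
#' Iterations in which fewer than two features survive the screen are
#' skipped (with a summary warning); more than 20% skipped is an error.
#'
#' @param table a [feature_table()].
#' @param cfg a [cv_config()].
#' @return An object of class `cv_result`; see Details for the main
#'   elements (`rmsep_mean`, `rmsep_sd`, `chosen_a`, `selection_freq`,
#'   `final_features`, `final_model`, `final_vip`, `evar`, the pooled
#'   cross-validated `q2` and prediction `test_r2`, and per-iteration
#'   records in `iterations`).
#' @export
monte_carlo_cv <- function(table, cfg = cv_config()) {
  X <- table$X; y <- table$y
  n <- nrow(X); m <- ncol(X)
  if (n < 2 * cfg$n_folds)
    warning("fewer than 2 rows per fold; test sets are very small",
            call. = FALSE)
  seeds <- spawn_seeds(cfg$seed, cfg$n_iter)
  fold_sizes <- rep(n %/% cfg$n_folds, cfg$n_folds) +
    c(rep(1L, n %% cfg$n_folds), rep(0L, cfg$n_folds - n %% cfg$n_folds))
  a_cap <- min(cfg$a_max, n - max(fold_sizes) - 1L, m)
  rmsep_mat <- matrix(NA_real_, cfg$n_iter, a_cap)
  press_mat <- matrix(NA_real_, cfg$n_iter, a_cap)   # test squared error
  ss_vec <- rep(NA_real_, cfg$n_iter)                # test SS about train mean
  evar_mat <- matrix(NA_real_, cfg$n_iter, a_cap)    # training per-comp R^2
  sel_mat <- matrix(FALSE, cfg$n_iter, m,
                    dimnames = list(NULL, colnames(X)))
  partitions <- matrix(NA_integer_, cfg$n_iter, n)
  pred_list <- vector("list", cfg$n_iter)   # held-out predictions per a
  skipped <- logical(cfg$n_iter)
  for (it in seq_len(cfg$n_iter)) {
    perm <- with_seed(seeds[it], sample.int(n))
    fold <- rep(seq_len(cfg$n_folds), times = fold_sizes)
    assign_f <- integer(n); assign_f[perm] <- fold
    partitions[it, ] <- assign_f
    test <- which(assign_f == cfg$n_folds)
    train <- which(assign_f != cfg$n_folds)
    scr <- select_features(X[train, , drop = FALSE], y[train], cfg$alpha)
    sel <- which(scr$selected)
    if (length(sel) < 2) { skipped[it] <- TRUE; next }
    sel_mat[it, sel] <- TRUE
    a_it <- min(a_cap, length(train) - 1L, length(sel))
    fit <- fit_pls1(feature_table(X[train, sel, drop = FALSE], y[train],
                                  ids = table$ids[train]), a_it)
    a_it <- fit$a_max
    ev <- explained_variation(fit)
    evar_mat[it, seq_len(a_it)] <- ev
    ss_vec[it] <- sum((y[test] - mean(y[train]))^2)
    pred_list[[it]] <- matrix(NA_real_, length(test), a_cap)
    for (a in seq_len(a_it)) {
      pred <- predict(fit, X[test, sel, drop = FALSE], a)
      rmsep_mat[it, a] <- rmsep(y[test], pred)
      press_mat[it, a] <- sum((y[test] - pred)^2)
      pred_list[[it]][, a] <- pred
    }
  }
  n_skip <- sum(skipped)
  if (n_skip > 0)
    warning(sprintf("%d of %d iterations skipped (fewer than 2 features selected)",
                    n_skip, cfg$n_iter), call. = FALSE)
  if (n_skip > 0.2 * cfg$n_iter)
    stop_itug("itug_harness_error",
              "%d of %d iterations skipped; screening too strict for this data",
              n_skip, cfg$n_iter)
  # the RMSEP curve only covers counts at least two iterations reached
  used <- colSums(!is.na(rmsep_mat)) >= 2
  rmsep_mean <- colMeans(rmsep_mat, na.rm = TRUE)[used]
  rmsep_sd <- apply(rmsep_mat[, used, drop = FALSE], 2, stats::sd,
                    na.rm = TRUE)
  chosen_a <- choose_components(rmsep_mean, rmsep_sd,
                                n_iter = sum(!skipped))
  selection_freq <- colMeans(sel_mat[!skipped, , drop = FALSE])
  final_features <- colnames(X)[selection_freq > cfg$selection_threshold]
  if (length(final_features) < 2) {
    # no stable selection (e.g. a null response): keep the object usable by
    # falling back to the two most frequently selected features
    warning(sprintf(
      "fewer than 2 features selected in more than %.0f%% of iterations; final model uses the 2 most frequent",
      100 * cfg$selection_threshold), call. = FALSE)
    final_features <- names(sort(selection_freq, decreasing = TRUE))[1:2]
  }
  final_a <- min(chosen_a, length(final_features), n - 1L)
  final_model <- fit_pls1(feature_table(X[, final_features, drop = FALSE],
                                        y, ids = table$ids), final_a)
  # explained variation across iterations, truncated at the chosen count;
  # components reached by fewer than 2 iterations cannot be summarised
  acols <- seq_len(min(chosen_a, ncol(evar_mat)))
  acols <- acols[colSums(!is.na(evar_mat[, acols, drop = FALSE])) >= 2]
  evar <- do.call(rbind, lapply(acols, function(a) {
    v <- evar_mat[, a]; v <- v[!is.na(v)]
    ci <- confidence_interval(v)
    data.frame(component = a, mean = mean(v), ci_lo = ci[1], ci_hi = ci[2])
  }))
  tot <- rowSums(evar_mat[, acols, drop = FALSE])
  tot <- tot[!is.na(tot)]
  ci_t <- confidence_interval(tot)
  evar <- rbind(evar, data.frame(component = NA, mean = mean(tot),
                                 ci_lo = ci_t[1], ci_hi = ci_t[2]))
  rownames(evar) <- NULL
  # pooled cross-validated Q^2: 1 - sum(PRESS)/sum(test SS), the standard
  # chemometrics estimator; pooling avoids the small-test-set ratio bias
  # of averaging per-iteration R^2 values
  q2 <- 1 - sum(press_mat[, chosen_a], na.rm = TRUE) /
    sum(ss_vec[!is.na(press_mat[, chosen_a])])
  # prediction R^2: squared correlation between pooled held-out
  # predictions (at the chosen component count) and the observed response,
  # the predicted-vs-measured accuracy of the scatter plot
  keep <- which(!skipped)
  yhat <- unlist(lapply(keep, function(it) pred_list[[it]][, chosen_a]))
  yobs <- unlist(lapply(keep, function(it)
    y[which(partitions[it, ] == cfg$n_folds)]))
  ok_p <- !is.na(yhat)   # iterations with fewer components than chosen
  test_r2 <- if (sum(ok_p) < 3 || stats::sd(yhat[ok_p]) == 0) 0 else
    stats::cor(yhat[ok_p], yobs[ok_p])^2
  structure(list(
    rmsep_mean = rmsep_mean, rmsep_sd = rmsep_sd, chosen_a = chosen_a,
    selection_freq = selection_freq, final_features = final_features,
    final_model = final_model,
    final_vip = vip(final_model, final_model$a_max),
    evar = evar,
    q2 = q2,
    test_r2 = test_r2,
    rmsep_iter_chosen = rmsep_mat[, chosen_a],
    iterations = list(partitions = partitions, selected = sel_mat,
                      rmsep = rmsep_mat, press = press_mat,
                      test_ss = ss_vec, skipped = skipped),
    config = cfg, n = n),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d iterations, chosen components: %d\n",
              x$config$n_iter, x$chosen_a))
  cat(sprintf("  RMSEP at chosen a: %.3f (SD %.3f)\n",
              x$rmsep_mean[x$chosen_a], x$rmsep_sd[x$chosen_a]))
  tot <- x$evar[is.na(x$evar$component), ]
  cat(sprintf("  total explained variation: %.3f (95%% CI %.3f-%.3f)\n",
              tot$mean, tot$ci_lo, tot$ci_hi))
  cat(sprintf("  %d features in final model\n", length(x$final_features)))
  invisible(x)
}

#' Paired comparison of two cross-validated models
#'
#' Both models must have been validated with the same seed and therefore
#' identical row partitions (same subjects, same folds), which makes the
#' per-iteration RMSEP values — each taken at its model's chosen component
#' count — a paired sample. The statistic is
#' `Z = mean(d) / (SD(d) / sqrt(n_iter))` with a two-sided normal p-value;
#' a model compared with itself gives `Z = 0`, `p = 1` by convention.
#' Negative `Z` favours model `a` (smaller prediction error).
#'
#' @param result_a,result_b two [monte_carlo_cv()] results on the same
#'   subjects with the same partitions.
#' @return An object of class `model_comparison` with `z`, `p` and the
#'   per-iteration differences `d` (a minus b).
#' @export
compare_models <- function(result_a, result_b) {
  if (!identical(result_a$iterations$partitions,
                 result_b$iterations$partitions))
    stop_itug("itug_pairing_error",
              "results were not validated on identical partitions")
  d <- result_a$rmsep_iter_chosen - result_b$rmsep_iter_chosen
  d <- d[!is.na(d)]
  if (length(d) < 2)
    stop_itug("itug_argument_error", "too few paired iterations")
  s <- stats::sd(d)
  z <- if (s == 0) 0 else mean(d) / (s / sqrt(length(d)))
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)), d = d,
                 n_iter = length(d)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> Z = %.3f, p = %.3g (n = %d paired iterations)\n",
              x$z, x$p, x$n_iter))
  cat(sprintf("  mean RMSEP difference (a - b): %.3f\n", mean(x$d)))
  invisible(x)
}
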