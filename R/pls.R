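# PLS1 regression core (NIPALS), explained variation, RMSEP and VIP.

#' Predictor/response container for the regression stage
#'
#' @param X numeric n x m matrix of predictors with unique column names.
#' @param y numeric response vector of length n (CBMS total score in the
#'   intended application).
#' @param ids optional subject identifiers.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(X, y, ids = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X)))
    stop_itug("itug_schema_error", "feature names must be unique")
  if (length(y) != nrow(X))
    stop_itug("itug_schema_error", "length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y))
    stop_itug("itug_schema_error",
              "feature table must not contain missing values at fit time")
  if (nrow(X) < 6)
    stop_itug("itug_argument_error", "need at least 6 rows, got %d", nrow(X))
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(X)))
  structure(list(X = X, y = as.numeric(y), ids = ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Fit a single-response partial least squares regression (PLS1)
#'
#' NIPALS algorithm for one response: predictors are z-scored (mandatory
#' for VIP comparability across features measured in different units) and
#' the response is centered. For each component the weight vector
#' `w_a` is proportional to `X_a' y_a` and normalized to unit length,
#' scores are `t_a = X_a w_a`, loadings `p_a = X_a' t_a / (t_a' t_a)` and
#' `q_a = y_a' t_a / (t_a' t_a)`, after which `X` and `y` are deflated.
#' Regression coefficients on the original scale are recoverable for every
#' component count `1..a_max` via [coef()] or [predict()].
#'
#' @param table a [feature_table()], or a matrix (then `y` is required).
#' @param a_max number of components, at most `min(n - 1, m)`.
#' @param y response vector when `table` is a bare matrix.
#' @return An object of class `pls1_model` with elements `weights`
#'   (m x A, unit-norm columns), `x_loadings`, `y_loadings`, `scores`,
#'   `ssy` (response sum of squares captured per component), the
#'   centering/scaling constants and `ss_tot` (total centered SS of y).
#' @export
fit_pls1 <- function(table, a_max, y = NULL) {
  if (!inherits(table, "feature_table")) table <- feature_table(table, y)
  X <- table$X; y <- table$y
  n <- nrow(X); m <- ncol(X)
  if (a_max < 1 || a_max > min(n - 1, m))
    stop_itug("itug_argument_error",
              "a_max must be in 1..min(n-1, m) = %d", min(n - 1, m))
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  if (any(sx == 0))
    stop_itug("itug_preprocessing_error",
              "zero-variance predictor column(s): %s",
              paste(colnames(X)[sx == 0], collapse = ", "))
  my <- mean(y)
  Xa <- scale(X, center = mx, scale = sx)
  ya <- y - my
  ss_tot <- sum(ya^2)
  W <- P <- matrix(0, m, a_max, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, a_max)
  q <- ssy <- numeric(a_max)
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { a_max <- a - 1L; break }
    w <- w / nw
    tt <- drop(Xa %*% w)
    t2 <- sum(tt^2)
    p <- drop(crossprod(Xa, tt)) / t2
    qa <- sum(ya * tt) / t2
    Xa <- Xa - tcrossprod(tt, p)
    ya <- ya - qa * tt
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; q[a] <- qa
    ssy[a] <- qa^2 * t2
  }
  if (a_max == 0)
    stop_itug("itug_preprocessing_error", "response carries no variance")
  keep <- seq_len(a_max)
  structure(list(weights = W[, keep, drop = FALSE],
                 x_loadings = P[, keep, drop = FALSE],
                 y_loadings = q[keep],
                 scores = Tm[, keep, drop = FALSE],
                 ssy = ssy[keep], ss_tot = ss_tot,
                 x_center = mx, x_scale = sx, y_center = my,
                 a_max = a_max, feature_names = colnames(X)),
            class = "pls1_model")
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("<pls1_model> %d features, %d components, cumulative R2 %.3f\n",
              length(x$feature_names), x$a_max, sum(x$ssy) / x$ss_tot))
  invisible(x)
}

#' Regression coefficients of a fitted PLS1 model
#'
#' @param object a `pls1_model`.
#' @param a number of components to use (default: all fitted).
#' @param ... unused.
#' @return Named vector of length m + 1: intercept followed by slopes on
#'   the original predictor scale.
#' @export
coef.pls1_model <- function(object, a = object$a_max, ...) {
  if (a < 0 || a > object$a_max)
    stop_itug("itug_argument_error", "a must be in 0..%d", object$a_max)
  if (a == 0) {
    b <- stats::setNames(rep(0, length(object$feature_names)),
                         object$feature_names)
    return(c(`(Intercept)` = object$y_center, b))
  }
  W <- object$weights[, seq_len(a), drop = FALSE]
  P <- object$x_loadings[, seq_len(a), drop = FALSE]
  bs <- drop(W %*% solve(crossprod(P, W), object$y_loadings[seq_len(a)]))
  b <- bs / object$x_scale
  c(`(Intercept)` = object$y_center - sum(b * object$x_center), b)
}

#' Predict from a fitted PLS1 model
#'
#' Applies the training centering/scaling constants to the new data (they
#' are never re-estimated from `X_new`) and evaluates the linear predictor
#' for the requested component count. `a = 0` returns the constant
#' training-mean prediction.
#'
#' @param object a `pls1_model`.
#' @param X_new matrix (or data.frame) with the same m columns the model
#'   was fitted on.
#' @param a number of components (default: all fitted).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1_model <- function(object, X_new, a = object$a_max, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$feature_names))
    stop_itug("itug_schema_error",
              "X_new has %d columns, model was fitted on %d",
              ncol(X_new), length(object$feature_names))
  b <- coef(object, a)
  drop(X_new %*% b[-1]) + b[1]
}

#' Per-component explained variation of the response
#'
#' The fraction of the total centered sum of squares of `y` captured by
#' each component; the cumulative sum is bounded by 1 and equals the OLS
#' R^2 when all `min(n - 1, m)` components are extracted from full-rank
#' data.
#'
#' @param model a `pls1_model`.
#' @return Numeric vector of per-component R^2 values.
#' @export
explained_variation <- function(model) {
  model$ssy / model$ss_tot
}

#' Root mean square error of prediction
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmsep <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    stop_itug("itug_argument_error",
              "y_true and y_pred must have equal positive length")
  sqrt(mean((y_true - y_pred)^2))
}

#' Variable importance in projection (VIP)
#'
#' Accumulated importance of each predictor over the first `a` components,
#' weighting the squared (unit-norm) weights by the response variance each
#' component captures:
#' `VIP_j = sqrt(m * sum_b ssy_b w_jb^2 / sum_b ssy_b)`.
#' The mean squared VIP over features is exactly 1.
#'
#' @param model a `pls1_model`.
#' @param a number of components to accumulate (default: all fitted).
#' @return Named vector of VIP scores.
#' @export
vip <- function(model, a = model$a_max) {
  if (a < 1 || a > model$a_max)
    stop_itug("itug_argument_error", "a must be in 1..%d", model$a_max)
  W2 <- model$weights[, seq_len(a), drop = FALSE]^2
  ssy <- model$ssy[seq_len(a)]
  m <- nrow(W2)
  sqrt(m * drop(W2 %*% ssy) / sum(ssy))
}

#' Classify VIP scores against the conventional cut-offs
#'
#' Bins each VIP value against the three cut-offs used for interpreting
#' predictor importance: 0.83 (lower), 1 (middle) and 1.21 (upper).
#' Boundary values fall in the upper bin.
#'
#' @param vips numeric vector of VIP scores.
#' @return Factor with levels `"<0.83"`, `"0.83-1"`, `"1-1.21"`, `">1.21"`.
#' @export
classify_vip <- function(vips) {
  cut(vips, breaks = c(-Inf, 0.83, 1, 1.21, Inf),
      labels = c("<0.83", "0.83-1", "1-1.21", ">1.21"),
      right = FALSE)
}

#' Serialize a fitted PLS1 model to JSON
#'
#' Writes every quantity needed to reproduce predictions — centering and
#' scaling constants, unit-norm weights, X/Y loadings, per-component
#' response sums of squares and feature names — as plain JSON.
#' [read_pls1()] restores a model whose predictions equal the original's.
#' Score vectors are not stored; they are training-data artefacts and are
#' not needed for prediction, coefficients or VIP.
#'
#' @param model a `pls1_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pls1 <- function(model, path) {
  payload <- list(
    format = "itug_pls1", version = 1L,
    feature_names = model$feature_names,
    x_center = unname(model$x_center), x_scale = unname(model$x_scale),
    y_center = model$y_center,
    weights = unname(model$weights), x_loadings = unname(model$x_loadings),
    y_loadings = model$y_loadings, ssy = model$ssy, ss_tot = model$ss_tot,
    a_max = model$a_max)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a PLS1 model written by [write_pls1()]
#'
#' @param path path to the JSON file.
#' @return A `pls1_model` (without training scores).
#' @export
read_pls1 <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "itug_pls1"))
    stop_itug("itug_io_error", "%s is not a serialized PLS1 model", path)
  m <- length(p$feature_names)
  shape <- function(x) matrix(x, nrow = m, ncol = p$a_max,
                              dimnames = list(p$feature_names, NULL))
  structure(list(weights = shape(p$weights),
                 x_loadings = shape(p$x_loadings),
                 y_loadings = p$y_loadings, scores = NULL,
                 ssy = p$ssy, ss_tot = p$ss_tot,
                 x_center = stats::setNames(p$x_center, p$feature_names),
                 x_scale = stats::setNames(p$x_scale, p$feature_names),
                 y_center = p$y_center, a_max = p$a_max,
                 feature_names = p$feature_names),
            class = "pls1_model")
}
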