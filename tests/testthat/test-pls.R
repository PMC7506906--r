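# PLS1 core: fitting, prediction, explained variation, RMSEP, VIP.

random_table <- function(n = 30, m = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  colnames(X) <- sprintf("V%02d", seq_len(m))
  y <- drop(X %*% rnorm(m)) + rnorm(n)
  feature_table(X, y)
}

test_that("a single informative column gives component-1 R^2 of 1", {
  set.seed(2)
  # mutually orthogonal, centred columns; y depends on the first only
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 3), 40, 3))))[, 2:4]
  colnames(Q) <- c("x1", "x2", "x3")
  y <- 3 * Q[, 1] - 1
  f <- fit_pls1(feature_table(Q, y), 1)
  expect_equal(explained_variation(f)[1], 1, tolerance = 1e-10)
})

test_that("full-component PLS1 reproduces ordinary least squares", {
  tab <- random_table(30, 10, seed = 3)
  f <- fit_pls1(tab, 10)
  ols <- lm.fit(cbind(1, tab$X), tab$y)
  expect_equal(unname(coef(f, 10)), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(predict(f, tab$X, 10)),
               unname(drop(cbind(1, tab$X) %*% ols$coefficients)),
               tolerance = 1e-8)
  # total explained variation equals the OLS R^2
  r2_ols <- 1 - sum(ols$residuals^2) / sum((tab$y - mean(tab$y))^2)
  expect_equal(sum(explained_variation(f)), r2_ols, tolerance = 1e-10)
})

test_that("the first weight vector is proportional to the y correlations", {
  tab <- random_table(25, 6, seed = 4)
  f <- fit_pls1(tab, 3)
  r <- drop(cor(tab$X, tab$y))
  w1 <- f$weights[, 1]
  expect_equal(unname(w1 / sqrt(sum(w1^2))),
               unname(r / sqrt(sum(r^2))) * sign(sum(w1 * r)),
               tolerance = 1e-10)
})

test_that("model invariants hold on every fit", {
  for (s in 1:5) {
    tab <- random_table(24, 8, seed = s)
    f <- fit_pls1(tab, 6)
    G <- crossprod(f$scores)
    expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
    expect_equal(unname(colSums(f$weights^2)), rep(1, f$a_max),
                 tolerance = 1e-10)
    ev <- explained_variation(f)
    expect_true(all(ev >= -1e-12))
    expect_lte(sum(ev), 1 + 1e-10)
  }
})

test_that("prediction applies training constants and handles edge cases", {
  tab <- random_table(30, 5, seed = 6)
  f <- fit_pls1(tab, 3)
  mu_row <- matrix(f$x_center, 1)
  for (a in 0:3)
    expect_equal(unname(predict(f, mu_row, a)), mean(tab$y),
                 tolerance = 1e-10)
  expect_error(predict(f, tab$X[, 1:3]), class = "itug_schema_error")
  expect_error(fit_pls1(tab, 50), class = "itug_argument_error")
  Xz <- tab$X; Xz[, 2] <- 1
  expect_error(fit_pls1(feature_table(Xz, tab$y), 2),
               "V02", class = "itug_preprocessing_error")
})

test_that("rmsep matches its definition", {
  expect_equal(rmsep(1:5, 1:5), 0)
  expect_equal(rmsep(1:5, 1:5 + 2), 2)
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(rmsep(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
  expect_error(rmsep(1:3, 1:4), class = "itug_argument_error")
})

test_that("VIP satisfies its algebraic identities", {
  # m = 1: normalization forces VIP = 1
  set.seed(9)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "only"))
  f1 <- fit_pls1(feature_table(x, 2 * x[, 1] + rnorm(30, 0, 0.1)), 1)
  expect_equal(unname(vip(f1)), 1, tolerance = 1e-10)

  # two exactly orthogonal centred predictors, y equal to the first:
  # the weight vector is (1, 0) and the VIPs are (sqrt(2), 0)
  n <- 40
  q <- cbind(a = rep(c(1, -1), n / 2), b = rep(c(1, 1, -1, -1), n / 4))
  f2 <- fit_pls1(feature_table(q, q[, 1]), 1)
  expect_equal(unname(vip(f2, 1)), c(sqrt(2), 0), tolerance = 1e-10)

  # sum of squared VIPs is the number of features
  for (s in 1:4) {
    tab <- random_table(25, 7, seed = 10 + s)
    f <- fit_pls1(tab, 4)
    for (a in 1:4)
      expect_equal(sum(vip(f, a)^2), 7, tolerance = 1e-8)
  }
  expect_error(vip(f1, 5), class = "itug_argument_error")
})

test_that("feature permutation permutes VIPs and loadings identically", {
  tab <- random_table(30, 8, seed = 15)
  f <- fit_pls1(tab, 4)
  perm <- c(3, 1, 8, 2, 5, 7, 4, 6)
  fp <- fit_pls1(feature_table(tab$X[, perm], tab$y), 4)
  expect_equal(unname(vip(fp, 4)), unname(vip(f, 4)[perm]), tolerance = 1e-9)
  expect_equal(unname(fp$x_loadings), unname(f$x_loadings[perm, ]),
               tolerance = 1e-9)
})

test_that("VIP classification uses the conventional cut-offs", {
  v <- c(0.5, 0.785, 0.83, 0.9, 1.0, 1.123, 1.21, 1.5)
  got <- as.character(classify_vip(v))
  expect_equal(got, c("<0.83", "<0.83", "0.83-1", "0.83-1", "1-1.21",
                      "1-1.21", ">1.21", ">1.21"))
})

test_that("coefficients agree with an independent PLS implementation", {
  requireNamespace("mixOmics", quietly = TRUE)
  tab <- random_table(30, 10, seed = 20)
  f <- fit_pls1(tab, 5)
  mo <- mixOmics::pls(tab$X, tab$y, ncomp = 5, mode = "regression",
                      scale = TRUE)
  for (a in 1:5) {
    pr_ref <- predict(mo, tab$X)$predict[, 1, a]
    pr_own <- predict(f, tab$X, a)
    expect_equal(unname(pr_own), unname(pr_ref), tolerance = 1e-6)
  }
})

test_that("model serialization round-trips predictions, VIP and R^2", {
  tab <- random_table(30, 8, seed = 30)
  f <- fit_pls1(tab, 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls1(f, path)
  g <- read_pls1(path)
  for (a in 1:4)
    expect_equal(predict(g, tab$X, a), predict(f, tab$X, a),
                 tolerance = 1e-12)
  expect_equal(vip(g, 4), vip(f, 4), tolerance = 1e-12)
  expect_equal(explained_variation(g), explained_variation(f),
               tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(read_pls1(bad), class = "itug_io_error")
})
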