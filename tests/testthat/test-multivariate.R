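# PCA against an SVD oracle; OPLS-DA against a NIPALS PLS1 oracle; VIP and
# prediction contracts.

test_that("PCA agrees with a direct SVD oracle up to sign", {
  set.seed(10)
  X <- matrix(rnorm(200), 10, 20)
  pc <- fit_pca(X, n_components = 4, scaling = "pareto")
  # oracle: scale independently, then svd
  mu <- apply(X, 2, mean); sdv <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sqrt(sdv), "/")
  sv <- svd(Xs)
  for (k in 1:4) {
    sgn <- sign(sum(pc$loadings[, k] * sv$v[, k]))
    expect_equal(pc$loadings[, k], sgn * sv$v[, k], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(pc$scores[, k], sgn * sv$u[, k] * sv$d[k],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(pc$explained_variance, sv$d[1:4]^2 / sum(sv$d^2),
               tolerance = 1e-10)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
})

test_that("PCA basics: dominant direction, orthogonal scores, bounds", {
  set.seed(11)
  u <- rnorm(15); v <- rnorm(30)
  X <- tcrossprod(u, v) + matrix(rnorm(450, sd = 1e-4), 15, 30)
  pc <- fit_pca(X, 2, scaling = "center")
  expect_gt(pc$explained_variance[1], 0.99)
  expect_lt(abs(cor(pc$scores[, 1], pc$scores[, 2])), 1e-8)
  expect_error(fit_pca(X, 15), "n_components")
})

test_that("OPLS-DA with n_ortho = 0 reproduces NIPALS PLS1 predictions", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 50), 20, 50)
    y <- rep(c("a", "b"), each = 10)
    y_num <- ifelse(y == "b", 1, -1)
    fit <- fit_opls_da(X, y, n_ortho = 0, scaling = "unit_variance",
                       positive_class = "b")
    oracle <- nipals_pls1(X, y_num, "unit_variance")
    set.seed(seed + 100)
    Xnew <- matrix(rnorm(5 * 50), 5, 50)
    expect_equal(predict(fit, Xnew)$y_hat, oracle$predict(Xnew),
                 tolerance = 1e-10)
    expect_equal(predict(fit, X)$y_hat, oracle$predict(X),
                 tolerance = 1e-10)
  }
})

test_that("OPLS-DA algebraic invariants hold on random data", {
  set.seed(3)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rep(c("a", "b"), c(13, 12))
  for (k in 0:3) {
    m <- fit_opls_da(X, y, n_ortho = k)
    expect_equal(sum(m$w^2), 1, tolerance = 1e-12)
    if (k > 0)
      for (j in seq_len(k))
        expect_lt(abs(sum(m$t * m$T_o[, j])),
                  1e-8 * sqrt(sum(m$t^2) * sum(m$T_o[, j]^2)))
    expect_true(m$R2X >= 0 && m$R2X <= 1)
    expect_true(m$R2Y >= 0 && m$R2Y <= 1)
  }
  # R2X non-decreasing in n_ortho on the same data
  r2x <- vapply(0:4, function(k) fit_opls_da(X, y, n_ortho = k)$R2X,
                numeric(1))
  expect_true(all(diff(r2x) >= -1e-10))
})

test_that("OPLS-DA rejects degenerate inputs", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_opls_da(X, rep("a", 10)), "two classes")
  expect_error(fit_opls_da(X, rep(c("a", "b"), 5), n_ortho = 4), "n_ortho")
  expect_error(fit_opls_da(X[1:3, ], c("a", "a", "b")), ">= 2 samples")
})

test_that("a planted separating bin dominates weights and VIP", {
  pm <- planted_matrix(n_per = 15, p = 40, planted = 7, delta = 6)
  m <- fit_opls_da(pm$X, pm$y, n_ortho = 1, positive_class = "trt")
  expect_identical(which.max(abs(m$w)), 7L)
  expect_gt(m$R2Y, 0.9)
  v <- vip(m)
  expect_identical(unname(which.max(v)), 7L)
  expect_equal(mean(v^2), 1, tolerance = 1e-12)
  # self-prediction on a well-separated cohort
  pr <- predict(m, pm$X)
  expect_gte(mean(pr$class == pm$y), 0.95)
})

test_that("VIP is sqrt(K)|w|: equal weights give VIP 1 everywhere", {
  # identical columns force equal weights
  set.seed(4)
  base <- rnorm(12)
  X <- matrix(base, 12, 5) + 0
  y <- rep(c("a", "b"), 6)
  m <- suppressWarnings(fit_opls_da(X, y, n_ortho = 0, scaling = "center"))
  expect_equal(unname(vip(m)), rep(1, 5), tolerance = 1e-10)
})

test_that("prediction is deterministic, name-checked, and ties go control", {
  pm <- planted_matrix()
  m <- fit_opls_da(pm$X, pm$y, n_ortho = 1, positive_class = "trt")
  pr1 <- predict(m, pm$X[3, , drop = FALSE])
  pr2 <- predict(m, pm$X)
  expect_equal(pr1$score, pr2$score[3], tolerance = 1e-12)
  # a row equal to the training-column means is all-zero after centering
  mid <- matrix(m$scaling$center, 1)
  colnames(mid) <- colnames(pm$X)
  prm <- predict(m, mid)
  expect_equal(prm$score, 0, tolerance = 1e-12)
  expect_identical(prm$class, "ctrl") # tie rule: control-like
  bad <- pm$X[, c(2:ncol(pm$X), 1)]
  expect_error(predict(m, bad), "column names")
  expect_error(predict(m, pm$X[, 1:5]), "columns")
})

test_that("scaling is learned on training rows only (no leakage)", {
  pm <- planted_matrix(seed = 12)
  train <- 1:20; test <- 21:30
  m <- fit_opls_da(pm$X[train, ], pm$y[train], n_ortho = 1,
                   positive_class = "trt")
  expect_equal(m$scaling$center, colMeans(pm$X[train, ]),
               ignore_attr = TRUE)
  # manual replay of the predict path with training parameters
  Xs <- sweep(sweep(pm$X[test, ], 2, m$scaling$center, "-"), 2,
              m$scaling$divisor, "/")
  t_o <- drop(Xs %*% m$W_o[, 1]); Xs <- Xs - tcrossprod(t_o, m$P_o[, 1])
  expect_equal(predict(m, pm$X[test, ])$score, drop(Xs %*% m$w),
               tolerance = 1e-12)
  # zero-variance columns get divisor 1 and a warning
  X0 <- pm$X[train, ]; X0[, 2] <- 5
  expect_warning(m0 <- fit_opls_da(X0, pm$y[train], positive_class = "trt"),
                 "zero-variance")
  expect_identical(unname(m0$scaling$divisor[2]), 1)
})
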