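test_that("one latent variable recovers a response carried by an orthogonal column", {
  # Helmert contrasts: columns are orthogonal with zero mean, so centering
  # leaves the design orthogonal and the first weight vector aligns exactly
  # with the informative column
  X <- stats::contr.helmert(12)[, 1:4]
  y <- 3 * X[, 2]
  m <- pls1_fit(X, y, 1)
  expect_equal(predict(m, X), y, tolerance = 1e-10)
})

test_that("full-rank PLS1 equals the ordinary-least-squares oracle", {
  set.seed(7)
  X <- matrix(stats::rnorm(12 * 4), 12, 4)
  y <- stats::rnorm(12)
  m <- pls1_fit(X, y, 4)
  # centered normal-equations oracle
  Xc <- scale(X, scale = FALSE)
  b <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  ols <- drop(Xc %*% b) + mean(y)
  expect_equal(predict(m, X), ols, tolerance = 1e-8)
})

test_that("latent-variable counts outside the rank limits are rejected", {
  X <- matrix(stats::rnorm(20), 5, 4)
  y <- stats::rnorm(5)
  expect_error(pls1_fit(X, y, 0), "positive integer")
  expect_error(pls1_fit(X, y, 5), "rank limit")
})

test_that("RMSECV matches a naive per-fold refit oracle", {
  set.seed(11)
  X <- matrix(stats::rnorm(18 * 6), 18, 6)
  y <- rep(1:3, each = 6) + stats::rnorm(18, sd = 0.3)
  folds <- cv_folds(18, 6, "blocks")
  for (a in c(1, 3)) {
    naive <- sqrt(mean(unlist(lapply(unique(folds), function(f) {
      m <- pls1_fit(X[folds != f, ], y[folds != f], a)
      (predict(m, X[folds == f, , drop = FALSE]) - y[folds == f])^2
    }))))
    expect_equal(rmsecv(X, y, a, k_folds = 6), naive, tolerance = 1e-10)
  }
  # permutation of samples together with their fold labels changes nothing
  perm <- sample(18)
  expect_equal(rmsecv(X[perm, ], y[perm], 3, folds = folds[perm]),
               rmsecv(X, y, 3, folds = folds), tolerance = 1e-10)
})

test_that("noiseless responses give near-zero leave-one-out RMSECV", {
  set.seed(2)
  # single predictor: one latent variable is simple regression
  x <- matrix(stats::rnorm(10), 10, 1)
  expect_lt(rmsecv(x, drop(2 * x), 1, k_folds = 10), 1e-8)
  # full rank on an exact linear response
  X <- matrix(stats::rnorm(30), 10, 3)
  y <- drop(X %*% c(1, -1, 2))
  expect_lt(rmsecv(X, y, 3, k_folds = 10), 1e-8)
})

test_that("folds with too few training samples are rejected", {
  X <- matrix(stats::rnorm(6 * 5), 6, 5)
  y <- stats::rnorm(6)
  expect_error(rmsecv(X, y, 5, k_folds = 2),
               "fewer training samples")
})

test_that("fold schemes are deterministic partitions", {
  f <- cv_folds(11, 3, "blocks")
  expect_identical(f, c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L))
  v <- cv_folds(7, 3, "venetian")
  expect_identical(v, c(1L, 2L, 3L, 1L, 2L, 3L, 1L))
  expect_error(cv_folds(5, 6), "2..n")
})

test_that("PCA matches an eigen-decomposition oracle", {
  # collinear cloud: first component explains everything
  t_ <- stats::rnorm(20)
  cloud <- cbind(2 * t_, -t_)
  p <- pca(cloud)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)

  set.seed(3)
  X <- matrix(stats::rnorm(12), 4, 3)
  p <- pca(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  k <- length(p$explained_variance)
  expect_equal(p$explained_variance,
               (ev$values / sum(ev$values))[seq_len(k)], tolerance = 1e-10)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-12)
  Xc <- scale(X, scale = FALSE)
  for (j in seq_len(k))
    expect_equal(abs(p$scores[, j]), abs(drop(Xc %*% ev$vectors[, j])),
                 tolerance = 1e-8)
  expect_error(pca(X[1, , drop = FALSE]), "at least 2")
})
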