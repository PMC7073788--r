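test_that("the every-third-from-sample-2 split gives the printed margins", {
  sp <- split_cal_pred(59, 3)
  expect_length(sp$within_prediction, 20)
  expect_identical(sp$within_prediction, seq(2L, 59L, 3L))
  expect_length(sp$calibration, 117)
  expect_length(sp$prediction, 60)
  # per-class margins 39 / 20
  cls <- rep(1:3, each = 59)
  expect_identical(as.integer(table(cls[sp$calibration])), rep(39L, 3))
  expect_identical(as.integer(table(cls[sp$prediction])), rep(20L, 3))

  expect_identical(split_cal_pred(3, 1)$within_prediction, 2L)
  sp6 <- split_cal_pred(6, 1)
  expect_identical(sp6$within_prediction, c(2L, 5L))
  expect_identical(sp6$calibration, c(1L, 3L, 4L, 6L))
  expect_error(split_cal_pred(1, 3), "at least 2")
})

test_that("dataset splitting agrees with the index rule", {
  ds <- generate_dataset(small_sim_config(n_samples_per_cultivar = 7))
  sp <- split_dataset(ds)
  ref <- split_cal_pred(7, 3)
  expect_identical(sp$prediction, ref$prediction)
  expect_identical(sp$calibration, ref$calibration)
})

test_that("SVM grid search scans 17 x 17 power-of-two pairs and separates a toy", {
  toy <- peak_shift_toy(n_per = 6, len = 20)
  m <- train_svm(toy$X, toy$y)
  expect_identical(dim(m$cv_grid), c(17L, 17L))
  expect_true(m$C %in% 2^(-8:8) && m$gamma %in% 2^(-8:8))
  expect_equal(m$training_accuracy, 1)
  expect_identical(predict_class(m, toy$X), toy$y)
  expect_error(train_svm(toy$X[1:6, ], toy$y[1:6]), "single class")
  expect_error(predict_class(m, toy$X[, 1:5]), "feature count")
})

test_that("exact-design RBF network interpolates distinct calibration samples", {
  toy <- peak_shift_toy(n_per = 5, len = 15, noise = 0.05, seed = 2)
  m <- train_rbfnn(toy$X, toy$y, spreads = 2)
  expect_equal(m$training_accuracy, 1)
  # tiny spread: each center dominates its own prediction
  m_small <- train_rbfnn(toy$X, toy$y, spreads = 0.5)
  expect_identical(predict_class(m_small, toy$X), toy$y)
  # the spread grid is scanned exhaustively in order
  m_grid <- train_rbfnn(toy$X, toy$y, spreads = 1:10)
  expect_identical(m_grid$cv_table$spread, 1:10)
  expect_error(predict_class(m, toy$X[, 1:3]), "feature count")
})

test_that("ELM output weights solve the hidden-layer least squares exactly", {
  toy <- peak_shift_toy(n_per = 6, len = 12, noise = 0.05, seed = 3)
  m <- train_elm(toy$X, toy$y, n_hidden_grid = 8, seed = 5)
  H <- 1 / (1 + exp(-(toy$X %*% m$W + rep(m$b, each = nrow(toy$X)))))
  Y <- libsseed:::one_hot(toy$y, 1:3)
  oracle <- qr.solve(H, Y)
  expect_equal(m$beta, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  # determinism under the seed
  m2 <- train_elm(toy$X, toy$y, n_hidden_grid = 8, seed = 5)
  expect_identical(m$beta, m2$beta)
  expect_identical(predict_class(m, toy$X), predict_class(m2, toy$X))
  # as many hidden neurons as samples: interpolation in generic position
  full <- train_elm(toy$X, toy$y, n_hidden_grid = nrow(toy$X), seed = 1)
  expect_equal(full$training_accuracy, 1)
  expect_error(train_elm(toy$X, toy$y, n_hidden_grid = 100), "exceed")
})

test_that("predictions permute with their samples", {
  toy <- peak_shift_toy(n_per = 5, len = 15, noise = 0.05, seed = 4)
  models <- list(
    train_svm(toy$X, toy$y, exponents = -2:2),
    train_rbfnn(toy$X, toy$y, spreads = 1:5),
    train_elm(toy$X, toy$y, n_hidden_grid = 10, seed = 2)
  )
  perm <- sample(nrow(toy$X))
  for (m in models) {
    p <- predict_class(m, toy$X)
    expect_identical(predict_class(m, toy$X[perm, ]), p[perm])
    expect_true(all(p %in% 1:3))
  }
})
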