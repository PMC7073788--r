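test_that("confusion matrices and accuracies follow the diagonal rules", {
  # three classes of 20 with 15, 18, 19 correct
  truth <- rep(1:3, each = 20)
  pred <- truth
  pred[1:5] <- c(2, 2, 2, 2, 3)      # class 1: 15 correct
  pred[21:22] <- 1                   # class 2: 18 correct
  pred[41] <- 2                      # class 3: 19 correct
  r <- confusion_and_accuracy(truth, pred)
  expect_equal(r$per_class, c(75, 90, 95))
  expect_equal(round(r$overall, 1), 86.7)
  expect_identical(sum(r$confusion), 60L)
  expect_identical(as.integer(rowSums(r$confusion)), rep(20L, 3))

  perfect <- confusion_and_accuracy(truth, truth)
  expect_equal(perfect$overall, 100)
  expect_identical(diag(perfect$confusion), c(`1` = 20L, `2` = 20L, `3` = 20L))

  constant <- confusion_and_accuracy(truth, rep(1L, 60))
  expect_equal(round(constant$overall, 1), 33.3)
  expect_error(confusion_and_accuracy(truth, rep(5L, 60)), "admissible")
  expect_error(confusion_and_accuracy(truth, pred[-1]), "length")
})

test_that("accuracies are invariant under a consistent relabeling", {
  set.seed(8)
  truth <- sample(1:3, 30, replace = TRUE)
  pred <- sample(1:3, 30, replace = TRUE)
  relab <- c(3L, 1L, 2L)
  a <- confusion_and_accuracy(truth, pred)
  b <- confusion_and_accuracy(relab[truth], relab[pred])
  expect_equal(a$overall, b$overall)
  expect_equal(sort(a$per_class), sort(b$per_class))
})

test_that("the Pearson branch equals the closed form and the chisq oracle", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    ca <- sample(5:(n - 5), 1)
    cb <- sample(5:(n - 5), 1)
    r <- compare_classifiers(ca, cb, n)
    tab <- rbind(c(ca, n - ca), c(cb, n - cb))
    if (r$test == "pearson") {
      oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(r$statistic, unname(oracle$statistic), tolerance = 1e-10)
      expect_equal(r$p_value, oracle$p.value, tolerance = 1e-10)
    }
  }
})

test_that("the Fisher branch matches exhaustive hypergeometric enumeration", {
  fisher_enum <- function(tab) {
    # two-sided exact test: sum the probabilities of all tables with the
    # same margins that are no more probable than the observed one
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n2):min(k, m)
    probs <- stats::dhyper(support, m, n2, k)
    p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(5)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    ca <- sample(0:n, 1)
    cb <- sample(0:n, 1)
    r <- compare_classifiers(ca, cb, n)
    tab <- rbind(c(ca, n - ca), c(cb, n - cb))
    expect_equal(stats::fisher.test(tab)$p.value, fisher_enum(tab),
                 tolerance = 1e-8)
    if (r$test == "fisher")
      expect_equal(r$p_value, fisher_enum(tab), tolerance = 1e-8)
  }
})

test_that("the test dispatch follows the expected-count rule and handles ties", {
  # 52 vs 57 of 60: all expected counts >= 5
  expect_identical(compare_classifiers(52, 57, 60)$test, "pearson")
  # 57 vs 58 of 60: expected incorrect counts fall below 5
  expect_identical(compare_classifiers(57, 58, 60)$test, "fisher")
  # identical results: p = 1 under either branch
  expect_equal(compare_classifiers(30, 30, 60)$p_value, 1)
  expect_equal(compare_classifiers(59, 59, 60)$p_value, 1)
  expect_error(compare_classifiers(5, 3, 0), "positive")
  expect_error(compare_classifiers(61, 3, 60), "0..n")
})

test_that("evaluation reports cover all pairwise comparisons and reproduce byte-for-byte", {
  toy <- peak_shift_toy(n_per = 8, len = 15, noise = 0.3, seed = 7)
  cal <- c(1:6, 9:14, 17:22)
  prd <- setdiff(seq_len(24), cal)
  models <- list(
    elm_a = train_elm(toy$X[cal, ], toy$y[cal], n_hidden_grid = 4, seed = 1),
    elm_b = train_elm(toy$X[cal, ], toy$y[cal], n_hidden_grid = 6, seed = 2),
    elm_c = train_elm(toy$X[cal, ], toy$y[cal], n_hidden_grid = 8, seed = 3),
    elm_d = train_elm(toy$X[cal, ], toy$y[cal], n_hidden_grid = 10, seed = 4)
  )
  rep1 <- evaluate_models(models, toy$X[cal, ], toy$y[cal],
                          toy$X[prd, ], toy$y[prd])
  expect_identical(nrow(rep1$comparisons), 6L)
  expect_true(all(rep1$comparisons$p_value >= 0 &
                    rep1$comparisons$p_value <= 1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(rep1, d1, manifest = list(seed = 1))
  write_report(rep1, d2, manifest = list(seed = 1))
  for (f in c("report.json", "accuracy.tsv", "comparisons.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
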