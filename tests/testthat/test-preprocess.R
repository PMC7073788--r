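make_ds <- function(wl, mat, labels = rep(1L, nrow(mat))) {
  libsseed:::new_spectral_dataset(wl, mat, labels)
}

test_that("range trimming keeps the closed interval and stays aligned", {
  ds <- make_ds(c(1, 2, 3), rbind(c(10, 20, 30), c(1, 2, 3)), c(1L, 2L))
  tr <- trim_range(ds, 1.5, 2.5)
  expect_identical(tr$wavelengths, 2)
  expect_identical(as.numeric(tr$intensities), c(20, 2))
  # identity bounds and idempotence
  full <- trim_range(ds, 1, 3)
  expect_identical(full$intensities, ds$intensities)
  expect_identical(trim_range(tr, 1.5, 2.5)$intensities, tr$intensities)
  expect_error(trim_range(ds, 10, 20), "empty axis")
})

test_that("the default analysis window holds 13,435 variables on the default axis", {
  ds <- generate_dataset(zero_noise_config(n_samples_per_cultivar = 1))
  tr <- trim_range(ds)
  expect_identical(ncol(tr$intensities), 13435L)
  expect_gte(min(tr$wavelengths), 380.01)
  expect_lte(max(tr$wavelengths), 860.04)
})

test_that("negative clipping is elementwise max(x, 0) and idempotent", {
  expect_identical(clip_negatives(c(-1, 2, -0.3)), c(0, 2, 0))
  x <- c(0, 1, 5)
  expect_identical(clip_negatives(x), x)
  y <- stats::rnorm(50)
  expect_identical(clip_negatives(clip_negatives(y)), clip_negatives(y))
})

test_that("the db6 transform reconstructs perfectly and denoising behaves", {
  # transform round-trip without thresholding is the identity
  filt <- libsseed:::wavelet_filters("db6")
  for (n in c(101, 256, 677)) {
    set.seed(n)
    x <- stats::rnorm(n)
    dec <- libsseed:::wavedec(x, filt, 3)
    expect_equal(libsseed:::waverec(dec, filt), x, tolerance = 1e-10)
  }
  # constant signal passes through unchanged (zero details)
  expect_equal(wavelet_denoise(rep(3.7, 200)), rep(3.7, 200),
               tolerance = 1e-10)
  # pure noise loses variance
  vr <- vapply(1:10, function(s) {
    set.seed(s)
    z <- stats::rnorm(600)
    stats::var(wavelet_denoise(z)) / stats::var(z)
  }, numeric(1))
  expect_true(all(vr < 1))
  expect_lt(stats::median(vr), 0.5)
  # a noiseless isolated emission peak keeps its height within 5%
  cfg <- small_sim_config(noise_sd = 0, sample_rsd = 0, global_rsd = 0)
  cfg$lines <- cfg$lines[cfg$lines$center_nm == 416.70, ]
  s <- simulate_shot(cultivar_profile(cfg, 1), cfg)
  expect_equal(max(wavelet_denoise(s)), max(s), tolerance = 0.05)
})

test_that("too-short inputs for the decomposition are rejected with the minimum", {
  expect_error(wavelet_denoise(stats::rnorm(50), level = 3), "88")
})

test_that("min-max normalization maps onto [0, 1] and is affine-invariant", {
  expect_identical(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  for (s in 1:5) {
    set.seed(s)
    x <- stats::rnorm(40)
    nx <- minmax_normalize(x)
    expect_identical(range(nx), c(0, 1))
    a <- stats::runif(1, 0.1, 5)
    b <- stats::rnorm(1)
    expect_equal(minmax_normalize(a * x + b), nx, tolerance = 1e-12)
  }
  expect_error(minmax_normalize(rep(2, 5)), "degenerate")
})

test_that("the pipeline applies trim, clip, denoise, normalize in order", {
  cfg <- small_sim_config(seed = 4)
  ds <- generate_dataset(cfg)
  pcfg <- preprocess_config(trim_lo = 385, trim_hi = 445)
  pp <- preprocess_pipeline(ds, pcfg)
  manual <- trim_range(ds, 385, 445)
  x <- clip_negatives(manual$intensities)
  x <- t(apply(x, 1, wavelet_denoise))
  x <- minmax_normalize(x, scope = "spectrum")
  expect_identical(pp$intensities, x)
  expect_identical(nrow(pp$intensities), nrow(ds$intensities))
  expect_true(all(pp$intensities >= 0 & pp$intensities <= 1))
  # deterministic
  expect_identical(preprocess_pipeline(ds, pcfg)$intensities, pp$intensities)
})

test_that("zero-noise spectra keep their peak positions through the pipeline", {
  ds <- generate_dataset(zero_noise_config(
    n_samples_per_cultivar = 2, lambda_min = 380, lambda_max = 450,
    resolving_power = 4000))
  pp <- preprocess_pipeline(ds, preprocess_config(trim_lo = 385,
                                                  trim_hi = 445))
  keep <- ds$wavelengths >= 385 & ds$wavelengths <= 445
  raw <- ds$intensities[, keep, drop = FALSE]
  for (i in seq_len(nrow(raw)))
    expect_identical(which.max(pp$intensities[i, ]), which.max(raw[i, ]))
})

test_that("configuration validates eagerly", {
  expect_error(preprocess_config(wavelet_name = "sym4"), "unsupported wavelet")
  expect_error(preprocess_config(trim_lo = 5, trim_hi = 2), "below")
  expect_error(preprocess_config(decomposition_level = 0), ">= 1")
})
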