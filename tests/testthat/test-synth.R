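test_that("a noiseless shot is the superposition of its line profiles", {
  lines <- data.frame(center_nm = c(400, 420), fwhm_nm = c(0.2, 0.2),
                      species = c("A", "B"), base_intensity = c(1, 2),
                      m1 = 1, m2 = 1, m3 = 1)
  base <- small_sim_config(noise_sd = 0, sample_rsd = 0, global_rsd = 0,
                           baseline_coef = numeric(0))
  both <- sim_config(noise_sd = 0, sample_rsd = 0, global_rsd = 0,
                     baseline_coef = numeric(0), lines = lines,
                     lambda_min = 380, lambda_max = 450,
                     resolving_power = 4000)
  one <- function(keep) {
    cfg <- both
    cfg$lines <- lines[keep, , drop = FALSE]
    simulate_shot(cultivar_profile(cfg, 1), cfg)
  }
  shot <- simulate_shot(cultivar_profile(both, 1), both)
  expect_equal(shot, one(1) + one(2), tolerance = 1e-12)
  # unit-height single line peaks at the grid point nearest its center
  cfg1 <- both
  cfg1$lines <- data.frame(center_nm = 412.34, fwhm_nm = 0.2, species = "A",
                           base_intensity = 1, m1 = 1, m2 = 1, m3 = 1)
  prof <- cultivar_profile(cfg1, 1)
  s <- simulate_shot(prof, cfg1)
  expect_identical(which.max(s), which.min(abs(prof$wavelengths - 412.34)))
  expect_lte(max(s), 1)
})

test_that("shots and samples are deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 5)
  prof <- cultivar_profile(cfg, 2)
  set.seed(99); a <- simulate_shot(prof, cfg)
  set.seed(99); b <- simulate_shot(prof, cfg)
  expect_identical(a, b)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$intensities, ds2$intensities)
})

test_that("a sample is the mean of 80 shots and inherits the averaged noise level", {
  cfg <- small_sim_config(noise_sd = 0, sample_rsd = 0, global_rsd = 0)
  expect_identical(cfg$n_craters * cfg$n_accumulations, 80L)
  prof <- cultivar_profile(cfg, 1)
  # zero noise: the averaged sample equals any single shot
  expect_equal(simulate_sample(prof, cfg), simulate_shot(prof, cfg),
               tolerance = 1e-12)
  # averaging 80 shots shrinks the noise variance to sd^2/80
  cfgn <- small_sim_config(noise_sd = 12, sample_rsd = 0, global_rsd = 0,
                           baseline_coef = numeric(0))
  cfgn$lines <- cfgn$lines[0, ]  # pure noise, clean spectrum is zero
  profn <- cultivar_profile(cfgn, 1)
  pooled <- unlist(lapply(1:20, function(s) {
    set.seed(s)
    simulate_sample(profn, cfgn)
  }))
  expect_equal(stats::var(pooled), 12^2 / 80, tolerance = 0.1)
})

test_that("zero shots are rejected", {
  expect_error(sim_config(n_craters = 0), "positive")
  cfg <- small_sim_config()
  cfg$n_craters <- 0L  # bypass construction checks
  expect_error(simulate_sample(cultivar_profile(cfg, 1), cfg),
               "at least one shot")
})

test_that("generated datasets have the full design and ground-truth class signal", {
  cfg <- small_sim_config(seed = 2)
  ds <- generate_dataset(cfg)
  expect_identical(dim(ds$intensities),
                   c(3L * cfg$n_samples_per_cultivar,
                     length(ds$wavelengths)))
  expect_identical(as.integer(table(ds$labels)), rep(9L, 3))
  expect_identical(ds$within_order, rep(1:9, 3))
  # class-mean intensity at the CN 416.70 nm line scales with the multipliers
  clean <- zero_noise_config(lambda_min = 380, lambda_max = 450,
                             resolving_power = 4000,
                             n_samples_per_cultivar = 2)
  dsc <- generate_dataset(clean)
  ch <- which.min(abs(dsc$wavelengths - 416.70))
  base <- libsseed:::baseline_curve(dsc$wavelengths, clean$baseline_coef)[ch]
  at_line <- tapply(dsc$intensities[, ch] - base, dsc$labels, mean)
  mult <- unlist(clean$lines[clean$lines$center_nm == 416.70,
                             c("m1", "m2", "m3")])
  expect_equal(as.numeric(at_line / at_line[1]),
               as.numeric(mult / mult[1]), tolerance = 0.05)
})

test_that("datasets round-trip through the delimited text format", {
  ds <- generate_dataset(small_sim_config(n_samples_per_cultivar = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  manifest <- withr::local_tempfile(fileext = ".json")
  write_dataset(ds, path, manifest)
  back <- read_dataset(path)
  expect_equal(back$wavelengths, ds$wavelengths, tolerance = 1e-8)
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$sample_ids, ds$sample_ids)
  mf <- jsonlite::read_json(manifest)
  expect_identical(mf$n_samples, 6L)
  expect_identical(mf$seed, 1L)
  expect_length(mf$line_table, nrow(ds$config$lines))
})
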