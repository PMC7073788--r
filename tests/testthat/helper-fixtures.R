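# Shared fixtures, all generated in code. Heavy study-scale objects are
# cached for the session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small axis (~680 channels over 380-450 nm) for fast unit tests
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples_per_cultivar = 9, lambda_min = 380, lambda_max = 450,
         resolving_power = 4000, noise_sd = 10, seed = 1),
    list(...))
  do.call(sim_config, args)
}

# even smaller profile for end-to-end pipeline runs
tiny_run_config <- function(seed = 3, out_dir) {
  cfg <- default_run_config(seed = seed, out_dir = out_dir)
  cfg$sim$n_samples_per_cultivar <- 6
  cfg$sim$lambda_min <- 380
  cfg$sim$lambda_max <- 440
  cfg$sim$resolving_power <- 3000
  cfg$ipls$k_min <- 3
  cfg$ipls$k_max <- 4
  cfg$classifiers$svm_exponent_min <- -2
  cfg$classifiers$svm_exponent_max <- 2
  cfg$classifiers$rbfnn_spread_max <- 10
  cfg$cnn$profile <- "desk"
  cfg$cnn$epochs <- 4
  cfg
}

zero_noise_config <- function(...) {
  args <- utils::modifyList(
    list(noise_sd = 0, sample_rsd = 0, global_rsd = 0, seed = 1),
    list(...))
  do.call(sim_config, args)
}

# study-scale default dataset (3 x 59 samples, full axis), preprocessed
default_preprocessed <- function(seed = 1) {
  cached(paste0("pp_default_", seed), {
    preprocess_pipeline(generate_dataset(sim_config(seed = seed)))
  })
}

# three-class toy with a class-dependent peak position, linearly separable
peak_shift_toy <- function(n_per = 13, len = 40, noise = 0, seed = 1) {
  set.seed(seed)
  mk <- function(pos) t(vapply(seq_len(n_per), function(i) {
    x <- numeric(len)
    x[pos + (-2:2)] <- c(0.3, 0.7, 1, 0.7, 0.3)
    x + noise * stats::rnorm(len)
  }, numeric(len)))
  pos <- pmin(pmax(round(len * c(0.25, 0.5, 0.75)), 3), len - 2)
  list(X = rbind(mk(pos[1]), mk(pos[2]), mk(pos[3])),
       y = rep(1:3, each = n_per))
}
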