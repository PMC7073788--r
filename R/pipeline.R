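#' Default run configuration
#'
#' Nested configuration for the one-command study: simulation, preprocessing,
#' iPLS region selection, classifier training on the full and selected
#' regions, and evaluation. Every field is serializable; \code{run_all}
#' echoes the resolved configuration into the run manifest.
#'
#' @param seed master seed for the whole run.
#' @param out_dir output directory.
#' @return a nested list of class \code{"run_config"}.
#' @export
default_run_config <- function(seed = 1, out_dir = "libsseed_run") {
  structure(
    list(
      seed = as.integer(seed),
      out_dir = out_dir,
      regions = c("full", "selected"),
      sim = list(
        n_cultivars = 3, n_samples_per_cultivar = 59, n_craters = 16,
        n_accumulations = 5, noise_sd = 30, heteroscedastic = FALSE,
        sample_rsd = 0.08, global_rsd = 0.10, peak_shape = "lorentzian",
        lambda_min = 230, lambda_max = 880, resolving_power = NULL
      ),
      preprocess = list(
        trim_lo = 380.01, trim_hi = 860.04, wavelet_name = "db6",
        decomposition_level = 3, normalization_scope = "spectrum"
      ),
      ipls = list(
        k_min = 10, k_max = 30, max_latent = 15, cv_scheme = "blocks",
        k_folds = 10
      ),
      classifiers = list(
        svm_exponent_min = -8, svm_exponent_max = 8,
        rbfnn_spread_max = 100, cv_folds = 5
      ),
      cnn = list(
        profile = "full", epochs = NULL, learning_rate = NULL,
        batch_size = 20, weight_decay = 1e-4, final_relu = TRUE
      )
    ),
    class = "run_config"
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", here, " must be a mapping")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, fills unset fields with defaults, rejects unknown keys
#' by name, and validates eagerly (e.g. an invalid wavelet name fails here,
#' before any computation). An empty file yields the default configuration.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_run_config()), user)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  do.call(preprocess_config, cfg$preprocess)
  if (cfg$ipls$k_min > cfg$ipls$k_max) stop("ipls: k_min exceeds k_max")
  if (!all(cfg$regions %in% c("full", "selected")))
    stop("regions must be a subset of {full, selected}")
  if (!cfg$cnn$profile %in% c("full", "desk"))
    stop("cnn profile must be \"full\" or \"desk\"")
  invisible(cfg)
}

resolve_cnn_config <- function(cfg) {
  base <- if (cfg$cnn$profile == "desk") cnn_desk_config(seed = cfg$seed)
          else cnn_train_config(seed = cfg$seed)
  if (!is.null(cfg$cnn$epochs)) base$epochs <- as.integer(cfg$cnn$epochs)
  if (!is.null(cfg$cnn$learning_rate))
    base$learning_rate <- cfg$cnn$learning_rate
  base$batch_size <- as.integer(cfg$cnn$batch_size)
  base$weight_decay <- cfg$cnn$weight_decay
  base
}

stage_log <- function(log_path, stage, t0) {
  msg <- sprintf("[%s] stage %-12s done in %.1fs", format(Sys.time()),
                 stage, as.numeric(Sys.time()) - t0)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

#' Run the complete study
#'
#' Executes every stage in order — simulate, preprocess, PCA, iPLS region
#' selection, training of the four classifier families on the full and
#' iPLS-selected regions, evaluation — persisting every intermediate
#' artifact under \code{config$out_dir} so each stage can be audited and
#' re-run. Training stages receive calibration data only; prediction-set
#' labels are first read at the evaluation stage.
#'
#' @param config a \code{run_config} (see \code{\link{default_run_config}}
#'   and \code{\link{load_config}}).
#' @return invisibly, a list with the run directory, the iPLS result and
#'   one \code{evaluation_report} per region.
#' @export
run_all <- function(config = default_run_config()) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)

  t0 <- as.numeric(Sys.time())
  sim_args <- config$sim
  sim_args$seed <- config$seed
  scfg <- do.call(sim_config, sim_args)
  dataset <- generate_dataset(scfg)
  write_dataset(dataset, file.path(config$out_dir, "dataset.csv"),
                file.path(config$out_dir, "dataset_manifest.json"))
  stage_log(log_path, "simulate", t0)

  t0 <- as.numeric(Sys.time())
  pcfg <- do.call(preprocess_config, config$preprocess)
  pp <- preprocess_pipeline(dataset, pcfg)
  write_dataset(pp, file.path(config$out_dir, "preprocessed.csv"))
  stage_log(log_path, "preprocess", t0)

  t0 <- as.numeric(Sys.time())
  pc <- pca(pp, n_components = 3)
  jsonlite::write_json(
    list(explained_variance = pc$explained_variance,
         scores = pc$scores),
    file.path(config$out_dir, "pca.json"), digits = NA)
  stage_log(log_path, "pca", t0)

  split <- split_dataset(pp)
  Xcal <- pp$intensities[split$calibration, , drop = FALSE]
  ycal <- pp$labels[split$calibration]
  Xprd <- pp$intensities[split$prediction, , drop = FALSE]
  yprd <- pp$labels[split$prediction]

  t0 <- as.numeric(Sys.time())
  ipls_res <- ipls_select(Xcal, ycal,
                          k_range = config$ipls$k_min:config$ipls$k_max,
                          max_latent = config$ipls$max_latent,
                          cv_scheme = config$ipls$cv_scheme,
                          k_folds = config$ipls$k_folds,
                          wavelengths = pp$wavelengths)
  jsonlite::write_json(
    list(best = ipls_res$best, global = ipls_res$global[c("rmsecv", "n_latent")]),
    file.path(config$out_dir, "ipls.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(ipls_res$table,
                     file.path(config$out_dir, "ipls_rmsecv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log(log_path, "ipls", t0)

  exps <- config$classifiers$svm_exponent_min:config$classifiers$svm_exponent_max
  spreads <- seq_len(config$classifiers$rbfnn_spread_max)
  kf <- config$classifiers$cv_folds
  cnn_cfg <- resolve_cnn_config(config)
  reports <- list()
  for (region in config$regions) {
    cols <- if (region == "full") seq_len(ncol(Xcal))
            else ipls_res$best$start:ipls_res$best$end
    Xc <- Xcal[, cols, drop = FALSE]
    Xp <- Xprd[, cols, drop = FALSE]
    t0 <- as.numeric(Sys.time())
    models <- list(
      svm = train_svm(Xc, ycal, exponents = exps, k_folds = kf),
      rbfnn = train_rbfnn(Xc, ycal, spreads = spreads, k_folds = kf),
      elm = train_elm(Xc, ycal, seed = config$seed, k_folds = kf),
      cnn = train_cnn(build_cnn(length(cols),
                                final_relu = config$cnn$final_relu),
                      Xc, ycal, cnn_cfg)
    )
    stage_log(log_path, paste0("train_", region), t0)
    t0 <- as.numeric(Sys.time())
    rep <- evaluate_models(models, Xc, ycal, Xp, yprd)
    manifest <- list(
      region = region, columns = range(cols), seed = config$seed,
      config = unclass(config),
      selected_interval = ipls_res$best,
      hyperparameters = list(
        svm = list(C = models$svm$C, gamma = models$svm$gamma),
        rbfnn = list(spread = models$rbfnn$spread),
        elm = list(n_hidden = models$elm$n_hidden, seed = models$elm$seed),
        cnn = unclass(cnn_cfg)
      )
    )
    write_report(rep, file.path(config$out_dir, paste0("region_", region)),
                 manifest = manifest)
    stage_log(log_path, paste0("evaluate_", region), t0)
    reports[[region]] <- rep
  }
  invisible(list(dir = config$out_dir, dataset = pp, ipls = ipls_res,
                 reports = reports))
}
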