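#' Emission-line table of the default simulator
#'
#' Ground truth for the synthetic LIBS spectra: each row is one emission line
#' with its center, full width at half maximum, species tag, base intensity
#' (arbitrary units) and one intensity multiplier per cultivar. The cultivar
#' signal is confined to the Sr II ionic line (407.78 nm), the CN molecular
#' band heads (416.70, 418.07, 419.65, 421.51 nm) and the Ca I atomic line
#' (422.66 nm); every other line is common to all three cultivars, so the
#' discriminating information lives in a narrow window around 403-427 nm.
#'
#' @return a data.frame with columns \code{center_nm}, \code{fwhm_nm},
#'   \code{species}, \code{base_intensity}, \code{m1}, \code{m2}, \code{m3}.
#' @export
default_line_table <- function() {
  tab <- rbind(
    # class-informative lines (the simulated cultivar signal)
    c(407.78, 0.10, "Sr II", 900,  1.00, 1.25, 0.75),
    c(416.70, 0.14, "CN",    1100, 1.00, 1.30, 1.60),
    c(418.07, 0.14, "CN",    950,  1.00, 1.25, 1.55),
    c(419.65, 0.14, "CN",    850,  1.00, 1.35, 1.65),
    c(421.51, 0.14, "CN",    700,  1.00, 1.20, 1.45),
    c(422.66, 0.10, "Ca I",  1300, 1.00, 0.80, 1.20),
    # common matrix lines, identical across cultivars
    c(385.99, 0.10, "Fe I",  500,  1, 1, 1),
    c(393.37, 0.10, "Ca II", 2600, 1, 1, 1),
    c(396.85, 0.10, "Ca II", 2200, 1, 1, 1),
    c(445.48, 0.10, "Ca I",  700,  1, 1, 1),
    c(589.00, 0.10, "Na I",  1800, 1, 1, 1),
    c(589.59, 0.10, "Na I",  1500, 1, 1, 1),
    c(656.28, 0.16, "H I",   1200, 1, 1, 1),
    c(746.83, 0.12, "N I",   900,  1, 1, 1),
    c(766.49, 0.12, "K I",   2400, 1, 1, 1),
    c(769.90, 0.12, "K I",   2000, 1, 1, 1),
    c(777.19, 0.12, "O I",   1600, 1, 1, 1)
  )
  data.frame(
    center_nm = as.numeric(tab[, 1]),
    fwhm_nm = as.numeric(tab[, 2]),
    species = tab[, 3],
    base_intensity = as.numeric(tab[, 4]),
    m1 = as.numeric(tab[, 5]),
    m2 = as.numeric(tab[, 6]),
    m3 = as.numeric(tab[, 7]),
    stringsAsFactors = FALSE
  )
}

#' Simulator configuration
#'
#' Collects every knob of the synthetic LIBS dataset: the acquisition design
#' (3 cultivars x 59 pellets, 16 ablation craters x 5 accumulations = 80 shots
#' averaged per pellet), the emission-line table, the noise model, and the
#' master seed from which all per-sample random substreams derive.
#'
#' @param n_cultivars number of classes (default 3).
#' @param n_samples_per_cultivar pellets per cultivar (default 59).
#' @param n_craters ablation positions per pellet (default 16, a 4 x 4 array).
#' @param n_accumulations accumulated spectra per position (default 5).
#' @param noise_sd standard deviation of the additive per-channel shot noise
#'   (arbitrary intensity units).
#' @param heteroscedastic if TRUE, the shot-noise sd scales with the square
#'   root of the local clean intensity (photon-noise-like); off by default.
#' @param sample_rsd relative sd of the per-sample, per-line lognormal
#'   intensity jitter (pellet-to-pellet compositional variability).
#' @param global_rsd relative sd of the per-sample global intensity scale
#'   (ablation-efficiency variability common to all lines of a shot series).
#' @param baseline_coef polynomial continuum coefficients in the scaled
#'   coordinate u = (lambda - min)/(max - min): intensity
#'   \code{c0 + c1*u + c2*u^2 + ...}.
#' @param peak_shape \code{"lorentzian"} (default; dominant broadening in
#'   atmospheric-pressure LIBS) or \code{"gaussian"}.
#' @param lines emission-line table, see \code{\link{default_line_table}}.
#' @param resolving_power axis resolving power; \code{NULL} uses the default
#'   calibrated axis (see \code{\link{default_axis}}).
#' @param lambda_min,lambda_max axis coverage (nm).
#' @param seed master seed; with the seed fixed the generated dataset is
#'   byte-identical across runs.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_cultivars = 3L,
                       n_samples_per_cultivar = 59L,
                       n_craters = 16L,
                       n_accumulations = 5L,
                       noise_sd = 30,
                       heteroscedastic = FALSE,
                       sample_rsd = 0.08,
                       global_rsd = 0.10,
                       baseline_coef = c(60, -30, 10),
                       peak_shape = c("lorentzian", "gaussian"),
                       lines = default_line_table(),
                       resolving_power = NULL,
                       lambda_min = 230,
                       lambda_max = 880,
                       seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  counts <- c(n_cultivars, n_samples_per_cultivar, n_craters, n_accumulations)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be positive integers")
  if (noise_sd < 0 || sample_rsd < 0 || global_rsd < 0)
    stop("noise scales must be non-negative")
  needed <- c("center_nm", "fwhm_nm", "species", "base_intensity",
              paste0("m", seq_len(n_cultivars)))
  if (!all(needed %in% names(lines)))
    stop("line table must provide one multiplier column per cultivar")
  if (any(lines$fwhm_nm <= 0) || any(lines$base_intensity < 0))
    stop("line widths must be positive and base intensities non-negative")
  structure(
    list(
      n_cultivars = as.integer(n_cultivars),
      n_samples_per_cultivar = as.integer(n_samples_per_cultivar),
      n_craters = as.integer(n_craters),
      n_accumulations = as.integer(n_accumulations),
      noise_sd = noise_sd,
      heteroscedastic = isTRUE(heteroscedastic),
      sample_rsd = sample_rsd,
      global_rsd = global_rsd,
      baseline_coef = baseline_coef,
      peak_shape = peak_shape,
      lines = lines,
      resolving_power = resolving_power,
      lambda_min = lambda_min,
      lambda_max = lambda_max,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

config_axis <- function(config) {
  if (is.null(config$resolving_power) &&
      config$lambda_min == 230 && config$lambda_max == 880) {
    default_axis()
  } else {
    rp <- config$resolving_power
    if (is.null(rp)) rp <- default_resolving_power()
    build_axis(config$lambda_min, config$lambda_max, rp)
  }
}

# unit-height peak profile on the axis
peak_profile <- function(wavelengths, center, fwhm, shape = "lorentzian") {
  if (shape == "lorentzian") {
    hw <- fwhm / 2
    hw^2 / ((wavelengths - center)^2 + hw^2)
  } else {
    exp(-4 * log(2) * (wavelengths - center)^2 / fwhm^2)
  }
}

# n_points x n_lines matrix of unit-height line shapes (computed once and
# reused for every sample: a clean spectrum is basis %*% heights + baseline)
line_basis <- function(wavelengths, lines, shape) {
  vapply(
    seq_len(nrow(lines)),
    function(i) peak_profile(wavelengths, lines$center_nm[i],
                             lines$fwhm_nm[i], shape),
    numeric(length(wavelengths))
  )
}

baseline_curve <- function(wavelengths, coef) {
  if (length(coef) == 0) return(numeric(length(wavelengths)))
  u <- (wavelengths - min(wavelengths)) /
    max(max(wavelengths) - min(wavelengths), .Machine$double.eps)
  drop(outer(u, seq_along(coef) - 1, `^`) %*% coef)
}

#' Per-cultivar emission profile
#'
#' Precomputes the noiseless emission spectrum of one cultivar on a given
#' axis: the sum of its line profiles (base intensity times the cultivar's
#' multiplier) plus the continuum baseline.
#'
#' @param config a \code{\link{sim_config}}.
#' @param cultivar cultivar index in \code{1..n_cultivars}.
#' @param axis optional precomputed \code{wavelength_axis}.
#' @return object of class \code{"cultivar_profile"} with the line heights,
#'   the precomputed line basis and clean spectrum.
#' @export
cultivar_profile <- function(config, cultivar, axis = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (cultivar < 1 || cultivar > config$n_cultivars)
    stop("cultivar index out of range")
  if (is.null(axis)) axis <- config_axis(config)
  wl <- axis_values(axis)
  if (length(wl) == 0) stop("axis is empty")
  mult <- config$lines[[paste0("m", cultivar)]]
  heights <- config$lines$base_intensity * mult
  basis <- line_basis(wl, config$lines, config$peak_shape)
  baseline <- baseline_curve(wl, config$baseline_coef)
  structure(
    list(cultivar = as.integer(cultivar), heights = heights, basis = basis,
         baseline = baseline, clean = drop(basis %*% heights) + baseline,
         wavelengths = wl),
    class = "cultivar_profile"
  )
}

#' Simulate a single laser shot
#'
#' One shot spectrum: the cultivar's clean emission spectrum plus zero-mean
#' Gaussian channel noise drawn from the current RNG state. Negative
#' intensities are possible (and expected at low signal), mirroring real
#' detector output before preprocessing.
#'
#' @param profile a \code{\link{cultivar_profile}}.
#' @param config a \code{\link{sim_config}} (noise model).
#' @param clean optional replacement clean spectrum (used internally to apply
#'   per-sample intensity jitter).
#' @return numeric intensity vector, one value per axis point.
#' @export
simulate_shot <- function(profile, config, clean = NULL) {
  stopifnot(inherits(profile, "cultivar_profile"))
  if (is.null(clean)) clean <- profile$clean
  if (length(clean) == 0) stop("axis is empty")
  if (config$noise_sd == 0) return(clean)
  sd_vec <- shot_noise_sd(clean, config)
  clean + stats::rnorm(length(clean), sd = sd_vec)
}

shot_noise_sd <- function(clean, config) {
  if (!config$heteroscedastic) return(config$noise_sd)
  pos <- pmax(clean, 0)
  config$noise_sd * sqrt(pos / max(mean(pos), .Machine$double.eps))
}

#' Simulate one pellet (sample) spectrum
#'
#' Applies the per-sample intensity jitter (a global ablation-efficiency
#' factor and independent per-line lognormal factors), draws
#' \code{n_craters * n_accumulations} shot spectra and returns their
#' arithmetic mean — the simulated counterpart of averaging 80 shots
#' (16 craters x 5 accumulations) per pellet.
#'
#' @inheritParams simulate_shot
#' @return numeric intensity vector (the averaged sample spectrum).
#' @export
simulate_sample <- function(profile, config) {
  stopifnot(inherits(profile, "cultivar_profile"))
  n_shots <- config$n_craters * config$n_accumulations
  if (n_shots < 1) stop("at least one shot is required")
  n <- length(profile$clean)
  heights <- profile$heights
  if (config$sample_rsd > 0)
    heights <- heights * stats::rlnorm(length(heights),
                                       meanlog = -config$sample_rsd^2 / 2,
                                       sdlog = config$sample_rsd)
  if (config$global_rsd > 0)
    heights <- heights * stats::rlnorm(1,
                                       meanlog = -config$global_rsd^2 / 2,
                                       sdlog = config$global_rsd)
  clean <- drop(profile$basis %*% heights) + profile$baseline
  if (config$noise_sd == 0) return(clean)
  sd_vec <- shot_noise_sd(clean, config)
  # mean of n_shots iid N(0, sd^2) channel draws == N(0, sd^2 / n_shots)
  clean + noise_mean_cpp(n, n_shots, sd_vec)
}

# deterministic per-sample substream seed below 2^31
sample_seed <- function(master_seed, sample_index) {
  as.integer((as.double(master_seed) * 1000003 +
                as.double(sample_index) * 7919) %% 2147483629) + 1L
}

#' Generate a full synthetic LIBS dataset
#'
#' Produces the complete study design: \code{n_cultivars} x
#' \code{n_samples_per_cultivar} averaged sample spectra in per-cultivar
#' acquisition order with integer labels 1..n_cultivars. Each sample uses a
#' seed derived deterministically from the master seed, so a fixed
#' \code{config$seed} yields a byte-identical dataset.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{"spectral_dataset"}: a list with
#'   \code{wavelengths}, \code{intensities} (samples x wavelengths matrix),
#'   \code{labels} (integer), \code{sample_ids}, \code{within_order}
#'   (1-based acquisition index within each cultivar) and the \code{config}.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  axis <- config_axis(config)
  wl <- axis_values(axis)
  n_per <- config$n_samples_per_cultivar
  n_tot <- config$n_cultivars * n_per
  intens <- matrix(NA_real_, nrow = n_tot, ncol = length(wl))
  labels <- integer(n_tot)
  within <- integer(n_tot)
  ids <- character(n_tot)
  row <- 0L
  for (cv in seq_len(config$n_cultivars)) {
    profile <- cultivar_profile(config, cv, axis = axis)
    for (j in seq_len(n_per)) {
      row <- row + 1L
      set.seed(sample_seed(config$seed, row))
      intens[row, ] <- simulate_sample(profile, config)
      labels[row] <- cv
      within[row] <- j
      ids[row] <- sprintf("C%d_S%02d", cv, j)
    }
  }
  new_spectral_dataset(wl, intens, labels, ids, within, config = config)
}

new_spectral_dataset <- function(wavelengths, intensities, labels,
                                 sample_ids = NULL, within_order = NULL,
                                 config = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(nrow(intensities)))
  if (is.null(within_order))
    within_order <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  stopifnot(nrow(intensities) == length(labels),
            ncol(intensities) == length(wavelengths))
  structure(
    list(wavelengths = as.numeric(wavelengths), intensities = intensities,
         labels = as.integer(labels), sample_ids = sample_ids,
         within_order = as.integer(within_order), config = config),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d wavelengths (%.2f-%.2f nm), labels: %s\n",
    nrow(x$intensities), ncol(x$intensities),
    min(x$wavelengths), max(x$wavelengths),
    paste(sprintf("%d x %d", table(x$labels),
                  sort(unique(x$labels))), collapse = ", ")
  ))
  invisible(x)
}

#' Write / read a spectral dataset as delimited text
#'
#' The on-disk format is a single comma-separated file: a header line with
#' \code{sample_id}, \code{cultivar} and the wavelength axis in nm, then one
#' line per sample with its id, integer label and intensities. An optional
#' JSON manifest records the generating configuration, seed and ground-truth
#' line table.
#'
#' @param dataset a \code{spectral_dataset}.
#' @param path output file path.
#' @param manifest_path optional path for the JSON manifest.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path, manifest_path = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  header <- paste(c("sample_id", "cultivar",
                    formatC(dataset$wavelengths, format = "g", digits = 10)),
                  collapse = ",")
  body <- vapply(seq_len(nrow(dataset$intensities)), function(i) {
    paste(c(dataset$sample_ids[i], dataset$labels[i],
            formatC(dataset$intensities[i, ], format = "g", digits = 10)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  if (!is.null(manifest_path)) {
    cfg <- dataset$config
    manifest <- list(
      n_samples = nrow(dataset$intensities),
      n_wavelengths = ncol(dataset$intensities),
      labels = as.integer(table(dataset$labels))
    )
    if (!is.null(cfg)) {
      manifest$seed <- cfg$seed
      manifest$config <- cfg[setdiff(names(cfg), "lines")]
      manifest$line_table <- cfg$lines
    }
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "sample_id")
    stop("not a libsseed dataset file")
  wl <- as.numeric(header[-(1:2)])
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  labels <- as.integer(vapply(parts, `[`, character(1), 2L))
  intens <- t(vapply(parts, function(p) as.numeric(p[-(1:2)]),
                     numeric(length(wl))))
  new_spectral_dataset(wl, intens, labels, ids)
}
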