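# Daubechies-6 analysis low-pass filter (orthonormal, 12 taps); the other
# three filters follow from the quadrature-mirror relations.
db6_dec_lo <- c(
  -0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
  -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
  -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
  0.7511339080210954, 0.49462389039845306, 0.11154074335010947
)

wavelet_filters <- function(wavelet_name) {
  if (!identical(wavelet_name, "db6"))
    stop("unsupported wavelet: ", wavelet_name, " (only \"db6\" is built in)")
  lo <- db6_dec_lo
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = length(lo))
}

conv_full <- function(x, f) conv_full_cpp(x, f)

# one analysis step: half-sample symmetric extension, filter, dyadic
# downsampling; coefficient length floor((n + fl - 1) / 2)
dwt_step <- function(x, filt) {
  n <- length(x)
  fl <- filt$length
  if (n < fl) stop("signal shorter than the wavelet filter")
  ext <- c(rev(x[1:(fl - 1)]), x, rev(x[(n - fl + 2):n]))
  len <- (n + fl - 1) %/% 2
  idx <- seq(fl + 1, by = 2, length.out = len)
  list(a = conv_full(ext, filt$dec_lo)[idx],
       d = conv_full(ext, filt$dec_hi)[idx])
}

# one synthesis step, trimmed to the target length (perfect reconstruction)
idwt_step <- function(a, d, filt, out_len) {
  up <- function(co) {
    u <- numeric(2 * length(co) - 1)
    u[seq(1, by = 2, length.out = length(co))] <- co
    u
  }
  rec <- conv_full(up(a), filt$rec_lo) + conv_full(up(d), filt$rec_hi)
  rec[seq(filt$length - 1, length.out = out_len)]
}

wavedec <- function(x, filt, level) {
  details <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (l in seq_len(level)) {
    lengths[l] <- length(a)
    st <- dwt_step(a, filt)
    details[[l]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, lengths = lengths)
}

waverec <- function(dec, filt) {
  a <- dec$approx
  for (l in rev(seq_along(dec$details)))
    a <- idwt_step(a, dec$details[[l]], filt, dec$lengths[l])
  a
}

#' Wavelet denoising of a spectrum
#'
#' Multilevel discrete wavelet transform (Daubechies 6, symmetric signal
#' extension), soft thresholding of all detail coefficients at the universal
#' threshold \eqn{\sigma\sqrt{2\log N}} — with \eqn{\sigma} estimated from the
#' median absolute deviation of the finest-level details — and reconstruction
#' to the original length. Smooth structure and isolated emission peaks pass
#' through essentially unchanged while broadband channel noise is suppressed.
#'
#' @param x numeric intensity vector.
#' @param wavelet_name wavelet basis; only \code{"db6"} is built in.
#' @param level decomposition level (default 3).
#' @return denoised vector of the same length as \code{x}.
#' @export
wavelet_denoise <- function(x, wavelet_name = "db6", level = 3) {
  filt <- wavelet_filters(wavelet_name)
  if (level < 1) stop("level must be >= 1")
  min_len <- (filt$length - 1) * 2^level
  if (length(x) < min_len)
    stop(sprintf("input of length %d is too short: a %d-level %s decomposition needs at least %d points",
                 length(x), level, wavelet_name, min_len))
  dec <- wavedec(x, filt, level)
  d1 <- dec$details[[1]]
  sigma <- stats::median(abs(d1 - stats::median(d1))) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  if (thr > 0) {
    dec$details <- lapply(dec$details, function(d)
      sign(d) * pmax(abs(d) - thr, 0))
  }
  waverec(dec, filt)
}

#' Trim a dataset to a closed wavelength interval
#'
#' Keeps the wavelengths with \code{lo <= lambda <= hi}; the axis and the
#' intensity columns stay aligned. The default bounds select the
#' 380.01-860.04 nm analysis window (13,435 channels on the default axis),
#' discarding the noisy extremes of the detection range.
#'
#' @param dataset a \code{spectral_dataset}.
#' @param lo,hi closed interval bounds in nm.
#' @return the trimmed \code{spectral_dataset}.
#' @export
trim_range <- function(dataset, lo = 380.01, hi = 860.04) {
  stopifnot(inherits(dataset, "spectral_dataset"), lo < hi)
  keep <- dataset$wavelengths >= lo & dataset$wavelengths <= hi
  if (!any(keep)) stop("trim produced empty axis")
  new_spectral_dataset(dataset$wavelengths[keep],
                       dataset$intensities[, keep, drop = FALSE],
                       dataset$labels, dataset$sample_ids,
                       dataset$within_order, dataset$config)
}

#' Clip negative intensities to zero
#'
#' Negative intensities produced by detector noise are set to zero; the
#' operation is the elementwise \code{max(x, 0)} and is idempotent.
#'
#' @param x numeric vector or matrix.
#' @return clipped object of the same shape.
#' @export
clip_negatives <- function(x) pmax(x, 0)

#' Min-max normalization to [0, 1]
#'
#' Affine rescaling \eqn{x^* = (x - min)/(max - min)}. With per-spectrum
#' scope each spectrum uses its own extremes and therefore attains both 0 and
#' 1 exactly; with dataset scope the extremes are taken over all spectra.
#'
#' @param x numeric vector, or matrix for \code{scope = "dataset"}.
#' @param scope \code{"spectrum"} (default) or \code{"dataset"}.
#' @return normalized object of the same shape, values in [0, 1].
#' @export
minmax_normalize <- function(x, scope = c("spectrum", "dataset")) {
  scope <- match.arg(scope)
  if (is.matrix(x) && scope == "spectrum") {
    return(t(apply(x, 1, minmax_normalize, scope = "spectrum")))
  }
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) stop("degenerate spectrum: max equals min")
  (x - lo) / (hi - lo)
}

#' Preprocessing configuration
#'
#' @param trim_lo,trim_hi analysis window bounds in nm.
#' @param wavelet_name wavelet basis for denoising.
#' @param decomposition_level DWT level.
#' @param normalization_scope \code{"spectrum"} or \code{"dataset"}.
#' @return object of class \code{"preprocess_config"}.
#' @export
preprocess_config <- function(trim_lo = 380.01, trim_hi = 860.04,
                              wavelet_name = "db6", decomposition_level = 3,
                              normalization_scope = c("spectrum", "dataset")) {
  normalization_scope <- match.arg(normalization_scope)
  if (trim_lo >= trim_hi) stop("trim_lo must be below trim_hi")
  if (decomposition_level < 1) stop("decomposition_level must be >= 1")
  wavelet_filters(wavelet_name)  # validates the name eagerly
  structure(
    list(trim_lo = trim_lo, trim_hi = trim_hi, wavelet_name = wavelet_name,
         decomposition_level = decomposition_level,
         normalization_scope = normalization_scope),
    class = "preprocess_config"
  )
}

#' Full preprocessing chain
#'
#' Applies, in order: range trimming to the analysis window, clipping of
#' negative intensities, wavelet denoising of every sample spectrum, and
#' min-max normalization. The sample count never changes.
#'
#' @param dataset a \code{spectral_dataset}.
#' @param config a \code{\link{preprocess_config}}.
#' @return the preprocessed \code{spectral_dataset}.
#' @export
preprocess_pipeline <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(config, "preprocess_config"))
  out <- trim_range(dataset, config$trim_lo, config$trim_hi)
  x <- clip_negatives(out$intensities)
  x <- t(apply(x, 1, wavelet_denoise, wavelet_name = config$wavelet_name,
               level = config$decomposition_level))
  x <- minmax_normalize(x, scope = if (config$normalization_scope == "spectrum")
    "spectrum" else "dataset")
  new_spectral_dataset(out$wavelengths, x, out$labels, out$sample_ids,
                       out$within_order, out$config)
}
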