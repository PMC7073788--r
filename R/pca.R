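#' Principal component analysis of a spectral dataset
#'
#' Mean-centered PCA (no variable scaling) used for an unsupervised overview
#' of the samples: orthonormal components sorted by explained variance.
#'
#' @param x a \code{spectral_dataset} or a numeric samples-x-variables matrix.
#' @param n_components number of components to retain (default: all).
#' @return list with \code{scores} (samples x components),
#'   \code{loadings} (variables x components, orthonormal columns) and
#'   \code{explained_variance} (fractions of total variance, non-increasing,
#'   summing to at most 1).
#' @export
pca <- function(x, n_components = NULL) {
  X <- if (inherits(x, "spectral_dataset")) x$intensities else as.matrix(x)
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  k <- if (is.null(n_components)) length(var_frac)
       else min(n_components, length(var_frac))
  list(
    scores = fit$x[, seq_len(k), drop = FALSE],
    loadings = fit$rotation[, seq_len(k), drop = FALSE],
    explained_variance = var_frac[seq_len(k)]
  )
}
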