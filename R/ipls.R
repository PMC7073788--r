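# sizes of k near-equal parts of n items, larger parts first
interval_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
}

#' Equidistant subintervals of the variable index range
#'
#' Splits variables 1..n_vars into k contiguous intervals whose sizes differ
#' by at most one; when n_vars is not divisible by k the larger intervals
#' come first. With 13,435 variables and k = 14 this puts 960 variables in
#' each of the first nine intervals and 959 in the last five.
#'
#' @param n_vars total number of variables.
#' @param k number of subintervals, 1..n_vars.
#' @return data.frame with columns \code{interval}, \code{start}, \code{end},
#'   \code{size} (1-based inclusive index ranges).
#' @export
split_intervals <- function(n_vars, k) {
  if (k < 1 || k > n_vars) stop("k must lie in 1..n_vars")
  sizes <- interval_sizes(n_vars, k)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  data.frame(interval = seq_len(k), start = as.integer(starts),
             end = as.integer(ends), size = as.integer(sizes))
}

#' Interval PLS spectral-region selection
#'
#' For every subdivision of the spectrum into k equidistant subintervals
#' (k over \code{k_range}), a local PLS1 model is cross-validated on each
#' subinterval with 1..\code{max_latent} latent variables; each interval
#' keeps the latent-variable count minimizing RMSECV (ties toward fewer).
#' The selected region is the interval with the lowest RMSECV over all
#' subdivisions. The full-spectrum (global) PLS model is cross-validated the
#' same way for reference.
#'
#' @param X preprocessed spectra matrix (samples x variables).
#' @param y numeric class codes (1/2/3).
#' @param k_range candidate subdivision counts (default 10:30).
#' @param max_latent maximum latent variables per local model (default 15).
#' @param cv_scheme,k_folds cross-validation scheme, see \code{\link{cv_folds}}.
#' @param wavelengths optional wavelength axis to annotate intervals in nm.
#' @return list of class \code{"ipls_result"}: \code{best} (selected interval
#'   with indices, wavelength range, latent count and RMSECV), \code{table}
#'   (per-interval RMSECV for every k) and \code{global} (full-spectrum
#'   RMSECV, latent count and RMSECV-vs-LV curve).
#' @export
ipls_select <- function(X, y, k_range = 10:30, max_latent = 15,
                        cv_scheme = "blocks", k_folds = 10,
                        wavelengths = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  folds <- cv_folds(n, k_folds, cv_scheme)
  if (any(k_range > ncol(X))) stop("k_range exceeds the variable count")

  best_of_curve <- function(curve) {
    a <- which.min(curve)  # which.min takes the first minimum: fewer LVs win ties
    list(n_latent = as.integer(a), rmsecv = curve[a])
  }

  g_curve <- rmsecv_curve(X, y, max_latent, folds)
  g_best <- best_of_curve(g_curve)

  rows <- vector("list", sum(k_range))
  ri <- 0L
  for (k in k_range) {
    iv <- split_intervals(ncol(X), k)
    for (i in seq_len(nrow(iv))) {
      cols <- iv$start[i]:iv$end[i]
      cap <- min(max_latent, length(cols))
      if (cap < max_latent)
        message(sprintf("interval %d of k=%d is narrower than %d variables; capping LVs at %d",
                        i, k, max_latent, cap))
      curve <- rmsecv_curve(X[, cols, drop = FALSE], y, cap, folds)
      b <- best_of_curve(curve)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        k = k, interval = i, start = iv$start[i], end = iv$end[i],
        size = iv$size[i],
        wl_lo = if (is.null(wavelengths)) NA_real_ else wavelengths[iv$start[i]],
        wl_hi = if (is.null(wavelengths)) NA_real_ else wavelengths[iv$end[i]],
        best_n_latent = b$n_latent, rmsecv = b$rmsecv
      )
    }
  }
  table <- do.call(rbind, rows[seq_len(ri)])
  sel <- which.min(table$rmsecv)  # ties: earliest (smaller k, earlier interval)
  structure(
    list(best = as.list(table[sel, ]), table = table,
         global = list(rmsecv = g_best$rmsecv, n_latent = g_best$n_latent,
                       curve = g_curve)),
    class = "ipls_result"
  )
}

#' @export
print.ipls_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<ipls_result> selected interval %d of k=%d: variables %d-%d (%d vars",
    b$interval, b$k, b$start, b$end, b$size))
  if (!is.na(b$wl_lo)) cat(sprintf(", %.2f-%.2f nm", b$wl_lo, b$wl_hi))
  cat(sprintf("), %d LVs, RMSECV = %.4f\n", b$best_n_latent, b$rmsecv))
  cat(sprintf("global model: %d LVs, RMSECV = %.4f\n",
              x$global$n_latent, x$global$rmsecv))
  invisible(x)
}
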