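#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares with a single numeric response, computed by the
#' NIPALS algorithm on mean-centered data (no variable scaling). Class codes
#' 1/2/3 are used directly as the response, following standard chemometric
#' practice for interval-based region selection. Models are nested in the
#' number of latent variables: one fit at \code{n_latent} yields the
#' regression vector for every smaller count.
#'
#' @param X numeric matrix (samples x variables).
#' @param y numeric response vector.
#' @param n_latent number of latent variables, between 1 and
#'   \code{min(nrow(X) - 1, ncol(X))}.
#' @return object of class \code{"pls1_model"} with weights \code{W},
#'   loadings \code{P}, response loadings \code{q}, centering offsets and the
#'   regression vector at \code{n_latent}.
#' @export
pls1_fit <- function(X, y, n_latent) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("X and y disagree in sample count")
  max_lv <- min(n - 1L, p)
  if (!is.numeric(n_latent) || n_latent < 1 || n_latent != round(n_latent))
    stop("n_latent must be a positive integer")
  if (n_latent > max_lv)
    stop(sprintf("n_latent = %d exceeds the rank limit min(n-1, p) = %d",
                 n_latent, max_lv))
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_means)
  yc <- y - y_mean
  A <- as.integer(n_latent)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  q <- numeric(A)
  Tt <- matrix(0, n, A)
  actual <- 0L
  for (h in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # response variance exhausted
    w <- w / nw
    t_sc <- drop(Xc %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- crossprod(Xc, t_sc) / tt
    q_h <- sum(yc * t_sc) / tt
    Xc <- Xc - tcrossprod(t_sc, p_load)
    yc <- yc - q_h * t_sc
    W[, h] <- w
    P[, h] <- p_load
    q[h] <- q_h
    Tt[, h] <- t_sc
    actual <- h
  }
  if (actual == 0L) stop("NIPALS could not extract any latent variable")
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  q <- q[seq_len(actual)]
  model <- structure(
    list(n_latent = actual, W = W, P = P, q = q, scores = Tt[, seq_len(actual), drop = FALSE],
         x_means = x_means, y_mean = y_mean),
    class = "pls1_model"
  )
  model$coefficients <- pls1_coefficients(model, actual)
  model
}

# regression vector using the first a latent variables of a fitted model
pls1_coefficients <- function(model, a) {
  a <- min(a, model$n_latent)
  W <- model$W[, seq_len(a), drop = FALSE]
  P <- model$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), model$q[seq_len(a)]))
}

#' @param object a \code{pls1_model}.
#' @param newdata numeric matrix of spectra to predict.
#' @param n_latent optional smaller latent-variable count to predict with.
#' @param ... unused.
#' @rdname pls1_fit
#' @export
predict.pls1_model <- function(object, newdata, n_latent = object$n_latent, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_means))
    stop("variable count does not match the fitted model")
  b <- if (n_latent == object$n_latent) object$coefficients
       else pls1_coefficients(object, n_latent)
  drop(sweep(newdata, 2, object$x_means) %*% b) + object$y_mean
}

#' Cross-validation fold assignment
#'
#' Deterministic fold schemes: \code{"blocks"} splits the sample order into k
#' contiguous blocks whose sizes differ by at most one (remainder to the
#' earliest blocks); \code{"venetian"} assigns sample i to fold
#' \code{((i - 1) mod k) + 1} (venetian-blind interleave).
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param scheme \code{"blocks"} (default) or \code{"venetian"}.
#' @return integer vector of fold labels in 1..k.
#' @export
cv_folds <- function(n, k = 10, scheme = c("blocks", "venetian")) {
  scheme <- match.arg(scheme)
  if (k < 2 || k > n) stop("k must lie in 2..n")
  k <- as.integer(k)
  if (scheme == "venetian") return(((seq_len(n) - 1L) %% k) + 1L)
  sizes <- interval_sizes(n, k)
  rep(seq_len(k), times = sizes)
}

# RMSECV for every latent-variable count 1..max_latent in one pass:
# one NIPALS fit per fold, nested coefficients for the smaller counts
rmsecv_curve <- function(X, y, max_latent, folds) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(folds) == n)
  min_train <- n - max(tabulate(folds))
  if (min_train < 1) stop("cross-validation fold leaves no training samples")
  cap <- min(max_latent, min_train - 1L, ncol(X))
  if (cap < 1) stop("no latent variable is estimable under this fold scheme")
  press <- numeric(cap)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- tryCatch(pls1_fit(X[tr, , drop = FALSE], y[tr], cap),
                      error = function(e) {
                        if (!grepl("could not extract", conditionMessage(e)))
                          stop(e)
                        NULL
                      })
    if (is.null(model)) {
      # degenerate fold (no covariance between X and y): intercept model
      press <- press + sum((mean(y[tr]) - y[!tr])^2)
      next
    }
    a_avail <- model$n_latent
    B <- vapply(seq_len(a_avail), function(a) pls1_coefficients(model, a),
                numeric(ncol(X)))
    preds <- sweep(X[!tr, , drop = FALSE], 2, model$x_means) %*% B +
      model$y_mean
    res2 <- (preds - y[!tr])^2
    contrib <- colSums(res2)
    if (a_avail < cap)  # rank-deficient fold: reuse the deepest model
      contrib <- c(contrib, rep(contrib[a_avail], cap - a_avail))
    press <- press + contrib
  }
  sqrt(press / n)
}

#' Root mean squared error of cross-validation
#'
#' Every sample is predicted exactly once by a PLS1 model fitted on the
#' remaining folds; RMSECV is the root mean square of those out-of-fold
#' residuals.
#'
#' @inheritParams pls1_fit
#' @param cv_scheme fold scheme, \code{"blocks"} or \code{"venetian"}.
#' @param k_folds number of folds (default 10).
#' @param folds optional explicit fold labels (overrides scheme).
#' @return RMSECV (non-negative scalar).
#' @export
rmsecv <- function(X, y, n_latent, cv_scheme = "blocks", k_folds = 10,
                   folds = NULL) {
  X <- as.matrix(X)
  if (is.null(folds)) folds <- cv_folds(nrow(X), k_folds, cv_scheme)
  n_latent <- as.integer(n_latent)
  for (f in unique(folds)) {
    if (sum(folds != f) < n_latent)
      stop("a fold has fewer training samples than the requested latent variables")
  }
  curve <- rmsecv_curve(X, y, n_latent, folds)
  if (length(curve) < n_latent)
    stop("a fold has fewer training samples than the requested latent variables")
  curve[n_latent]
}
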