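#' Calibration / prediction split
#'
#' Deterministic split used throughout: within each cultivar's acquisition
#' order, every third sample starting from sample 2 (indices 2, 5, 8, ...)
#' goes to the prediction set and the rest to the calibration set. With 59
#' samples per cultivar this gives 39 calibration and 20 prediction samples
#' per class.
#'
#' @param n_per_class samples per class (>= 2).
#' @param n_classes number of classes.
#' @return list with \code{calibration} and \code{prediction}: global row
#'   indices assuming samples ordered class by class, plus
#'   \code{within_prediction}, the within-class prediction indices.
#' @export
split_cal_pred <- function(n_per_class, n_classes = 3) {
  if (n_per_class < 2) stop("need at least 2 samples per class")
  n_per_class <- as.integer(n_per_class)
  within_pred <- seq(2L, n_per_class, by = 3L)
  offsets <- (seq_len(n_classes) - 1L) * n_per_class
  pred <- as.integer(outer(within_pred, offsets, `+`))
  all_idx <- seq_len(n_per_class * n_classes)
  list(calibration = setdiff(all_idx, pred), prediction = sort(pred),
       within_prediction = within_pred)
}

#' Split a spectral dataset by acquisition order
#'
#' Applies the every-third-starting-at-2 rule to each cultivar's
#' \code{within_order}.
#'
#' @param dataset a \code{spectral_dataset}.
#' @return list with \code{calibration} and \code{prediction} row indices.
#' @export
split_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  pred <- which(dataset$within_order %% 3L == 2L)
  list(calibration = setdiff(seq_along(dataset$labels), pred),
       prediction = pred)
}

# squared Euclidean cross-distances, rows of a vs rows of b
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

one_hot <- function(y, levels) {
  m <- matrix(0, length(y), length(levels))
  m[cbind(seq_along(y), match(y, levels))] <- 1
  m
}

classifier_cv_folds <- function(n, k_folds = 5) {
  # venetian interleave: with class-blocked sample order this keeps every
  # fold close to class-balanced
  cv_folds(n, min(k_folds, n), "venetian")
}

#' Train an RBF-kernel support vector machine
#'
#' One-vs-one multi-class SVM with a Gaussian kernel
#' \eqn{K(u,v) = \exp(-\gamma \|u-v\|^2)}. The penalty C and kernel width
#' gamma are chosen by exhaustive grid search over integer powers of two
#' \eqn{2^{-8}..2^{8}} (a 17 x 17 grid), scored by k-fold cross-validated
#' accuracy on the calibration set only; ties go to the first grid point in
#' (gamma, C) order. The kernel matrix is precomputed once per gamma.
#'
#' @param Xcal calibration spectra (samples x variables).
#' @param ycal integer class labels.
#' @param exponents power-of-two exponents for both C and gamma.
#' @param k_folds internal cross-validation folds (default 5).
#' @return a \code{trained_classifier} of family \code{"svm"} with the
#'   selected \code{C}, \code{gamma} and the grid of CV accuracies.
#' @export
train_svm <- function(Xcal, ycal, exponents = -8:8, k_folds = 5) {
  Xcal <- as.matrix(Xcal)
  yf <- factor(ycal)
  if (nlevels(yf) < 2) stop("calibration set contains a single class")
  grid_vals <- 2^exponents
  n <- nrow(Xcal)
  folds <- classifier_cv_folds(n, k_folds)
  D2 <- cross_dist2(Xcal, Xcal)
  best <- list(acc = -1, C = NA, gamma = NA)
  cv_grid <- matrix(NA_real_, length(grid_vals), length(grid_vals),
                    dimnames = list(gamma = as.character(grid_vals),
                                    C = as.character(grid_vals)))
  for (gi in seq_along(grid_vals)) {
    g <- grid_vals[gi]
    K <- exp(-g * D2)
    for (ci in seq_along(grid_vals)) {
      C <- grid_vals[ci]
      correct <- 0L
      for (f in sort(unique(folds))) {
        tr <- which(folds != f)
        va <- which(folds == f)
        m <- kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr]), yf[tr],
                           type = "C-svc", C = C)
        Kva <- kernlab::as.kernelMatrix(
          K[va, tr, drop = FALSE][, kernlab::SVindex(m), drop = FALSE])
        correct <- correct + sum(kernlab::predict(m, Kva) == yf[va])
      }
      acc <- correct / n
      cv_grid[gi, ci] <- acc
      if (acc > best$acc) best <- list(acc = acc, C = C, gamma = g)
    }
  }
  K <- exp(-best$gamma * D2)
  final <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc",
                         C = best$C)
  train_pred <- as.integer(as.character(kernlab::predict(
    final, kernlab::as.kernelMatrix(
      K[, kernlab::SVindex(final), drop = FALSE]))))
  structure(
    list(family = "svm", model = final, Xcal = Xcal, levels = levels(yf),
         C = best$C, gamma = best$gamma, cv_accuracy = best$acc,
         cv_grid = cv_grid,
         training_accuracy = mean(train_pred == as.integer(as.character(yf)))),
    class = c("libsseed_svm", "trained_classifier")
  )
}

#' @export
predict_class <- function(model, X) UseMethod("predict_class")

#' @export
predict_class.libsseed_svm <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$Xcal)) stop("feature count does not match training")
  K <- exp(-model$gamma * cross_dist2(X, model$Xcal))
  Kn <- kernlab::as.kernelMatrix(
    K[, kernlab::SVindex(model$model), drop = FALSE])
  as.integer(as.character(kernlab::predict(model$model, Kn)))
}

rbf_design <- function(D, spread) exp(-(0.8326 * D / spread)^2)

# least squares with a rank-deficiency fallback to a small ridge
lstsq_or_ridge <- function(A, B, note = NULL) {
  qa <- qr(A)
  if (qa$rank == ncol(A)) return(list(coef = qr.coef(qa, B), ridged = FALSE))
  if (!is.null(note)) message(note)
  ridge <- 1e-8 * max(1, mean(diag(crossprod(A))))
  G <- crossprod(A)
  diag(G) <- diag(G) + ridge
  list(coef = solve(G, crossprod(A, B)), ridged = TRUE)
}

#' Train an exact-design radial basis function network
#'
#' Three-layer feed-forward network with one Gaussian hidden unit centered on
#' every calibration sample. The hidden activation is
#' \eqn{\exp(-(0.8326\,\|x - c\| / s)^2)}, so a unit's output falls to 0.5 at
#' distance equal to the spread s. Linear output weights (one response per
#' class, plus bias) are solved by least squares onto one-hot targets;
#' prediction is the arg-max output. The spread is scanned over 1..100 (step
#' 1) by k-fold cross-validated accuracy on the calibration set.
#'
#' @inheritParams train_svm
#' @param spreads candidate spread values (default \code{1:100}).
#' @return a \code{trained_classifier} of family \code{"rbfnn"}.
#' @export
train_rbfnn <- function(Xcal, ycal, spreads = 1:100, k_folds = 5) {
  Xcal <- as.matrix(Xcal)
  levs <- sort(unique(as.integer(ycal)))
  Y <- one_hot(ycal, levs)
  n <- nrow(Xcal)
  folds <- classifier_cv_folds(n, k_folds)
  D <- sqrt(cross_dist2(Xcal, Xcal))
  ridged_any <- FALSE
  cv_acc <- numeric(length(spreads))
  for (si in seq_along(spreads)) {
    Phi <- rbf_design(D, spreads[si])
    correct <- 0L
    for (f in sort(unique(folds))) {
      tr <- which(folds != f)
      va <- which(folds == f)
      A <- cbind(1, Phi[tr, tr, drop = FALSE])
      fit <- lstsq_or_ridge(A, Y[tr, , drop = FALSE])
      ridged_any <- ridged_any || fit$ridged
      out <- cbind(1, Phi[va, tr, drop = FALSE]) %*% fit$coef
      correct <- correct + sum(levs[max.col(out, ties.method = "first")] ==
                                 ycal[va])
    }
    cv_acc[si] <- correct / n
  }
  best_i <- which.max(cv_acc)  # ties: smallest spread
  spread <- spreads[best_i]
  Phi <- rbf_design(D, spread)
  fit <- lstsq_or_ridge(cbind(1, Phi), Y,
                        note = "exact-design matrix is rank-deficient (duplicate or near-duplicate calibration samples): using a ridge-regularized solve")
  if (ridged_any && !fit$ridged)
    message("some cross-validation solves were ridge-regularized (near-duplicate samples)")
  out <- cbind(1, Phi) %*% fit$coef
  structure(
    list(family = "rbfnn", centers = Xcal, weights = fit$coef, levels = levs,
         spread = spread, cv_accuracy = cv_acc[best_i],
         cv_table = data.frame(spread = spreads, accuracy = cv_acc),
         training_accuracy = mean(levs[max.col(out, ties.method = "first")] ==
                                    ycal)),
    class = c("libsseed_rbfnn", "trained_classifier")
  )
}

#' @export
predict_class.libsseed_rbfnn <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$centers))
    stop("feature count does not match training")
  Phi <- rbf_design(sqrt(cross_dist2(X, model$centers)), model$spread)
  out <- cbind(1, Phi) %*% model$weights
  model$levels[max.col(out, ties.method = "first")]
}

# Moore-Penrose pseudoinverse solve via SVD; reports the condition number
# of the hidden matrix when it is numerically degenerate
pinv_solve <- function(A, B, warn_cond = 1e10) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sv$d[1] > 0 && (min(sv$d) == 0 || sv$d[1] / min(sv$d) > warn_cond))
    message(sprintf("hidden-layer matrix is ill-conditioned (condition number %.3g); using the pseudoinverse",
                    sv$d[1] / max(min(sv$d), .Machine$double.xmin)))
  sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], B))
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer feed-forward network with random input weights and
#' biases (uniform on [-1, 1], drawn once from \code{seed}) and sigmoid
#' hidden activation. Output weights are solved in closed form by the
#' Moore-Penrose pseudoinverse onto one-hot targets; prediction is the
#' arg-max output. The hidden-neuron count is scanned from 1 to the
#' calibration-set size by k-fold cross-validated accuracy (ties toward the
#' smallest network); candidate networks are nested, re-using the leading
#' columns of one weight draw.
#'
#' @inheritParams train_svm
#' @param n_hidden_grid candidate hidden-layer sizes (default
#'   \code{1:nrow(Xcal)}).
#' @param seed seed for the random input weights.
#' @return a \code{trained_classifier} of family \code{"elm"}.
#' @export
train_elm <- function(Xcal, ycal, n_hidden_grid = NULL, seed = 1,
                      k_folds = 5) {
  Xcal <- as.matrix(Xcal)
  n <- nrow(Xcal)
  p <- ncol(Xcal)
  if (is.null(n_hidden_grid)) n_hidden_grid <- seq_len(n)
  if (any(n_hidden_grid > n))
    stop("hidden-neuron count cannot exceed the calibration-set size")
  Lmax <- max(n_hidden_grid)
  levs <- sort(unique(as.integer(ycal)))
  Y <- one_hot(ycal, levs)
  set.seed(as.integer(seed))
  W <- matrix(stats::runif(p * Lmax, -1, 1), p, Lmax)
  b <- stats::runif(Lmax, -1, 1)
  H <- 1 / (1 + exp(-(Xcal %*% W + rep(b, each = n))))
  folds <- classifier_cv_folds(n, k_folds)
  cv_acc <- numeric(length(n_hidden_grid))
  for (li in seq_along(n_hidden_grid)) {
    L <- n_hidden_grid[li]
    correct <- 0L
    for (f in sort(unique(folds))) {
      tr <- which(folds != f)
      va <- which(folds == f)
      beta <- pinv_solve(H[tr, seq_len(L), drop = FALSE],
                         Y[tr, , drop = FALSE], warn_cond = Inf)
      out <- H[va, seq_len(L), drop = FALSE] %*% beta
      correct <- correct + sum(levs[max.col(out, ties.method = "first")] ==
                                 ycal[va])
    }
    cv_acc[li] <- correct / n
  }
  best_i <- which.max(cv_acc)  # first maximum: smallest network wins ties
  L <- n_hidden_grid[best_i]
  beta <- pinv_solve(H[, seq_len(L), drop = FALSE], Y)
  out <- H[, seq_len(L), drop = FALSE] %*% beta
  structure(
    list(family = "elm", W = W[, seq_len(L), drop = FALSE], b = b[seq_len(L)],
         beta = beta, levels = levs, n_hidden = L, seed = as.integer(seed),
         cv_accuracy = cv_acc[best_i],
         cv_table = data.frame(n_hidden = n_hidden_grid, accuracy = cv_acc),
         training_accuracy = mean(levs[max.col(out, ties.method = "first")] ==
                                    ycal)),
    class = c("libsseed_elm", "trained_classifier")
  )
}

#' @export
predict_class.libsseed_elm <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W)) stop("feature count does not match training")
  H <- 1 / (1 + exp(-(X %*% model$W + rep(model$b, each = nrow(X)))))
  out <- H %*% model$beta
  model$levels[max.col(out, ties.method = "first")]
}

#' @export
print.trained_classifier <- function(x, ...) {
  hp <- switch(x$family,
    svm = sprintf("C = %.4g, gamma = %.4g", x$C, x$gamma),
    rbfnn = sprintf("spread = %g", x$spread),
    elm = sprintf("hidden neurons = %d", x$n_hidden),
    cnn = sprintf("epochs = %d, lr = %g", x$config$epochs,
                  x$config$learning_rate),
    "")
  cat(sprintf("<trained_classifier:%s> %s; training accuracy %.1f%%\n",
              x$family, hp, 100 * x$training_accuracy))
  invisible(x)
}
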