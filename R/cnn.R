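#' Flatten size of the 1-D CNN
#'
#' Valid (unpadded) convolutions of kernel size 3 and a size-2/stride-2 max
#' pool give \code{16 * (floor((input_length - 2) / 2) - 2)} flattened
#' features.
#'
#' @param input_length number of spectral channels fed to the network.
#' @return integer flatten size.
#' @export
cnn_flatten_size <- function(input_length) {
  input_length <- as.integer(input_length)
  16L * (((input_length - 2L) %/% 2L) - 2L)
}

#' Build the 1-D convolutional network architecture
#'
#' Fixed layer stack for spectral classification into 3 classes:
#' conv(32 kernels, size 3, stride 1) + batch norm + ReLU; max pool (2, 2);
#' conv(16 kernels, size 3, stride 1) + batch norm (no activation);
#' dense 512 + batch norm + ReLU + dropout 0.5; dense 32 + batch norm +
#' ReLU + dropout 0.2; dense 3 (+ ReLU, switchable); softmax. Convolutional
#' and batch-normalized dense layers carry no additive bias (the batch-norm
#' shift plays that role).
#'
#' @param input_length spectral channels; must be at least 8 so the
#'   conv/pool stack leaves a positive length.
#' @param final_relu keep the ReLU on the 3-unit output layer before the
#'   softmax (the architecture's printed form); set FALSE for the
#'   conventional linear-logit variant.
#' @return object of class \code{"cnn_network"} describing every layer shape.
#' @export
build_cnn <- function(input_length, final_relu = TRUE) {
  input_length <- as.integer(input_length)
  l1 <- input_length - 2L          # after conv1 (valid, k = 3)
  l2 <- l1 %/% 2L                  # after max pool (2, 2); odd tail dropped
  l3 <- l2 - 2L                    # after conv2 (valid, k = 3)
  if (input_length < 8L || l3 < 1L)
    stop(sprintf("input_length %d is too short; the conv/pool stack needs at least 8 channels",
                 input_length))
  flat <- 16L * l3
  shapes <- list(
    W1 = c(3L, 32L), bn1_gamma = 32L, bn1_beta = 32L,
    W2 = c(96L, 16L), bn2_gamma = 16L, bn2_beta = 16L,
    Wd1 = c(flat, 512L), bn3_gamma = 512L, bn3_beta = 512L,
    Wd2 = c(512L, 32L), bn4_gamma = 32L, bn4_beta = 32L,
    Wd3 = c(32L, 3L), bd3 = 3L
  )
  structure(
    list(input_length = input_length, l1 = l1, l2 = l2, l3 = l3,
         flatten = flat, shapes = shapes, final_relu = isTRUE(final_relu),
         n_classes = 3L,
         n_parameters = sum(vapply(shapes, prod, numeric(1)))),
    class = "cnn_network"
  )
}

#' @export
print.cnn_network <- function(x, ...) {
  cat(sprintf(
    "<cnn_network> input %d -> conv32 %d -> pool %d -> conv16 %d -> flatten %d -> 512 -> 32 -> 3 (%s parameters)\n",
    x$input_length, x$l1, x$l2, x$l3, x$flatten,
    format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

#' Training configuration of the CNN
#'
#' Defaults are the full training recipe: Adam at learning rate 1e-5, batch
#' size 20, 1000 epochs, Xavier initialization, softmax cross-entropy loss,
#' dropout and weight decay against overfitting. \code{cnn_desk_config}
#' returns a desk-scale profile (100 epochs at learning rate 1e-3) for
#' reduced-size runs such as the test suite.
#'
#' @param batch_size minibatch size; the last incomplete batch is kept.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param weight_decay L2 coefficient applied to weight matrices (not to
#'   batch-norm parameters or biases).
#' @param seed seed for initialization and epoch shuffling.
#' @return object of class \code{"cnn_train_config"}.
#' @export
cnn_train_config <- function(batch_size = 20, learning_rate = 1e-5,
                             epochs = 1000, weight_decay = 1e-4, seed = 1) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1,
            weight_decay >= 0)
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         epochs = as.integer(epochs), weight_decay = weight_decay,
         seed = as.integer(seed), adam_beta1 = 0.9, adam_beta2 = 0.999,
         adam_eps = 1e-8, bn_momentum = 0.9, bn_eps = 1e-5,
         dropout1 = 0.5, dropout2 = 0.2),
    class = "cnn_train_config"
  )
}

#' @rdname cnn_train_config
#' @param ... overrides passed to \code{cnn_train_config}.
#' @export
cnn_desk_config <- function(...) {
  args <- utils::modifyList(list(epochs = 100, learning_rate = 1e-3),
                            list(...))
  do.call(cnn_train_config, args)
}

xavier_init <- function(shapes) {
  params <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    if (length(sh) == 2) {
      lim <- sqrt(6 / (sh[1] + sh[2]))
      params[[nm]] <- matrix(stats::runif(prod(sh), -lim, lim), sh[1], sh[2])
    } else if (grepl("gamma", nm)) {
      params[[nm]] <- rep(1, sh)
    } else {
      params[[nm]] <- rep(0, sh)
    }
  }
  params
}

# --- batch normalization over columns -------------------------------------

bn_forward <- function(X, gamma, beta, eps, training, run_mean, run_var) {
  if (training) {
    mv <- col_mean_var(X)
    inv_sd <- 1 / sqrt(mv$var + eps)
    xhat <- col_affine(X, inv_sd, -mv$mean * inv_sd)
    out <- col_affine(xhat, gamma, beta)
    list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma),
         mean = mv$mean, var = mv$var)
  } else {
    inv_sd <- 1 / sqrt(run_var + eps)
    out <- col_affine(col_affine(X, inv_sd, -run_mean * inv_sd), gamma, beta)
    list(out = out, cache = NULL)
  }
}

bn_backward <- function(dout, cache) {
  bn_backward_cpp(dout, cache$xhat, cache$inv_sd, cache$gamma)
}

# --- im2col helpers (rows are position-major: row = (pos-1)*b + sample) ----

conv_rows <- function(b, positions) {
  as.vector(outer(seq_len(b), (positions - 1L) * b, `+`))
}

im2col1 <- function(X, l_out) {
  # X: b x L input; returns (b*l_out) x 3 patch matrix
  cbind(as.vector(X[, 1:l_out, drop = FALSE]),
        as.vector(X[, 2:(l_out + 1), drop = FALSE]),
        as.vector(X[, 3:(l_out + 2), drop = FALSE]))
}

col2im1 <- function(dM, b, L, l_out) {
  dX <- matrix(0, b, L)
  for (o in 0:2) {
    dX[, (1 + o):(l_out + o)] <-
      dX[, (1 + o):(l_out + o)] + matrix(dM[, o + 1], b, l_out)
  }
  dX
}

# forward pass; returns probabilities plus every cache needed for backprop
cnn_forward <- function(net, params, X, cfg, training = FALSE, state = NULL) {
  b <- nrow(X)
  eps <- cfg$bn_eps
  cache <- list(b = b)

  M1 <- im2col1(X, net$l1)                       # (b*l1) x 3
  C1 <- M1 %*% params$W1                          # (b*l1) x 32
  bn1 <- bn_forward(C1, params$bn1_gamma, params$bn1_beta, eps, training,
                    state$bn1_mean, state$bn1_var)
  A1 <- pmax(bn1$out, 0)
  cache$M1 <- M1; cache$bn1 <- bn1$cache; cache$relu1 <- bn1$out > 0

  odd <- conv_rows(b, seq(1L, by = 2L, length.out = net$l2))
  even <- conv_rows(b, seq(2L, by = 2L, length.out = net$l2))
  P <- pmax(A1[odd, , drop = FALSE], A1[even, , drop = FALSE])  # (b*l2) x 32
  cache$pool <- list(odd = odd, even = even,
                     take_odd = A1[odd, , drop = FALSE] >=
                       A1[even, , drop = FALSE])

  r1 <- conv_rows(b, 1:net$l3)
  r2 <- conv_rows(b, 2:(net$l3 + 1L))
  r3 <- conv_rows(b, 3:(net$l3 + 2L))
  M2 <- cbind(P[r1, , drop = FALSE], P[r2, , drop = FALSE],
              P[r3, , drop = FALSE])              # (b*l3) x 96
  C2 <- M2 %*% params$W2                          # (b*l3) x 16
  bn2 <- bn_forward(C2, params$bn2_gamma, params$bn2_beta, eps, training,
                    state$bn2_mean, state$bn2_var)
  cache$M2 <- M2; cache$bn2 <- bn2$cache
  cache$conv2_rows <- list(r1 = r1, r2 = r2, r3 = r3)

  Fl <- matrix(as.vector(bn2$out), nrow = b)      # b x (l3*16)

  D1 <- Fl %*% params$Wd1
  bn3 <- bn_forward(D1, params$bn3_gamma, params$bn3_beta, eps, training,
                    state$bn3_mean, state$bn3_var)
  A3 <- pmax(bn3$out, 0)
  cache$Fl <- Fl; cache$bn3 <- bn3$cache; cache$relu3 <- bn3$out > 0
  if (training && cfg$dropout1 > 0) {
    mask1 <- matrix(stats::runif(length(A3)) >= cfg$dropout1,
                    nrow(A3), ncol(A3)) / (1 - cfg$dropout1)
    A3 <- A3 * mask1
    cache$drop1 <- mask1
  }

  D2 <- A3 %*% params$Wd2
  bn4 <- bn_forward(D2, params$bn4_gamma, params$bn4_beta, eps, training,
                    state$bn4_mean, state$bn4_var)
  A4 <- pmax(bn4$out, 0)
  cache$A3 <- A3; cache$bn4 <- bn4$cache; cache$relu4 <- bn4$out > 0
  if (training && cfg$dropout2 > 0) {
    mask2 <- matrix(stats::runif(length(A4)) >= cfg$dropout2,
                    nrow(A4), ncol(A4)) / (1 - cfg$dropout2)
    A4 <- A4 * mask2
    cache$drop2 <- mask2
  }

  Z <- sweep(A4 %*% params$Wd3, 2, params$bd3, `+`)
  cache$A4 <- A4
  if (net$final_relu) {
    cache$reluZ <- Z > 0
    Z <- pmax(Z, 0)
  }
  Zs <- Z - apply(Z, 1, max)
  expz <- exp(Zs)
  probs <- expz / rowSums(expz)

  bn_stats <- if (training)
    list(bn1 = list(bn1$mean, bn1$var), bn2 = list(bn2$mean, bn2$var),
         bn3 = list(bn3$mean, bn3$var), bn4 = list(bn4$mean, bn4$var))
  list(probs = probs, cache = cache, bn_stats = bn_stats)
}

cnn_backward <- function(net, params, fw, Y) {
  cache <- fw$cache
  b <- cache$b
  g <- list()

  dZ <- (fw$probs - Y) / b
  if (net$final_relu) dZ <- dZ * cache$reluZ
  g$Wd3 <- crossprod(cache$A4, dZ)
  g$bd3 <- colSums(dZ)
  dA4 <- tcrossprod(dZ, params$Wd3)
  if (!is.null(cache$drop2)) dA4 <- dA4 * cache$drop2
  dBn4 <- dA4 * cache$relu4
  bb4 <- bn_backward(dBn4, cache$bn4)
  g$bn4_gamma <- bb4$dgamma; g$bn4_beta <- bb4$dbeta
  g$Wd2 <- crossprod(cache$A3, bb4$dx)
  dA3 <- tcrossprod(bb4$dx, params$Wd2)
  if (!is.null(cache$drop1)) dA3 <- dA3 * cache$drop1
  dBn3 <- dA3 * cache$relu3
  bb3 <- bn_backward(dBn3, cache$bn3)
  g$bn3_gamma <- bb3$dgamma; g$bn3_beta <- bb3$dbeta
  g$Wd1 <- crossprod(cache$Fl, bb3$dx)
  dFl <- tcrossprod(bb3$dx, params$Wd1)

  dC2bn <- matrix(as.vector(dFl), nrow = b * net$l3)  # undo flatten
  bb2 <- bn_backward(dC2bn, cache$bn2)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  g$W2 <- crossprod(cache$M2, bb2$dx)
  dM2 <- tcrossprod(bb2$dx, params$W2)             # (b*l3) x 96

  dP <- matrix(0, b * net$l2, 32)
  cr <- cache$conv2_rows
  dP[cr$r1, ] <- dP[cr$r1, ] + dM2[, 1:32]
  dP[cr$r2, ] <- dP[cr$r2, ] + dM2[, 33:64]
  dP[cr$r3, ] <- dP[cr$r3, ] + dM2[, 65:96]

  dA1 <- matrix(0, b * net$l1, 32)
  pool <- cache$pool
  dA1[pool$odd, ] <- dP * pool$take_odd
  dA1[pool$even, ] <- dA1[pool$even, ] + dP * (!pool$take_odd)

  dBn1 <- dA1 * cache$relu1
  bb1 <- bn_backward(dBn1, cache$bn1)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  g$W1 <- crossprod(cache$M1, bb1$dx)
  g
}

#' Train the 1-D CNN
#'
#' Minimizes the softmax cross-entropy loss with Adam. Labels 1..3 are
#' mapped to one-hot targets internally; batch-norm statistics and dropout
#' are active only during training, and running statistics accumulated over
#' minibatches serve inference. The per-epoch mean training loss is logged;
#' a non-finite loss aborts with diagnostics.
#'
#' @param network a \code{\link{build_cnn}} architecture.
#' @param Xcal calibration spectra (samples x \code{input_length}).
#' @param ycal labels in 1..3.
#' @param config a \code{\link{cnn_train_config}}.
#' @param verbose print the loss every 10 epochs.
#' @return a \code{trained_classifier} of family \code{"cnn"} carrying the
#'   fitted parameters, batch-norm running statistics and the loss history.
#' @export
train_cnn <- function(network, Xcal, ycal, config = cnn_train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(network, "cnn_network"),
            inherits(config, "cnn_train_config"))
  Xcal <- as.matrix(Xcal)
  if (ncol(Xcal) != network$input_length)
    stop("input length does not match the network")
  levs <- 1:3
  if (!all(ycal %in% levs)) stop("labels must lie in {1, 2, 3}")
  n <- nrow(Xcal)
  Y <- one_hot(ycal, levs)
  set.seed(config$seed)
  params <- xavier_init(network$shapes)
  zero_like <- function(p) if (is.matrix(p)) p * 0 else numeric(length(p))
  adam_m <- lapply(params, zero_like)
  adam_v <- lapply(params, zero_like)
  state <- list()
  for (l in paste0("bn", 1:4)) {
    width <- length(params[[paste0(l, "_gamma")]])
    state[[paste0(l, "_mean")]] <- numeric(width)
    state[[paste0(l, "_var")]] <- rep(1, width)
  }
  decay_set <- c("W1", "W2", "Wd1", "Wd2", "Wd3")
  mom <- config$bn_momentum
  step <- 0L
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      fw <- cnn_forward(network, params, Xcal[idx, , drop = FALSE], config,
                        training = TRUE, state = state)
      pb <- fw$probs[cbind(seq_along(idx), ycal[idx])]
      loss <- -mean(log(pmax(pb, 1e-12)))
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d (batch starting %d); inspect learning rate and inputs",
                     epoch, s))
      epoch_loss <- epoch_loss + loss * length(idx)
      for (l in names(fw$bn_stats)) {
        st <- fw$bn_stats[[l]]
        state[[paste0(l, "_mean")]] <- mom * state[[paste0(l, "_mean")]] +
          (1 - mom) * st[[1]]
        state[[paste0(l, "_var")]] <- mom * state[[paste0(l, "_var")]] +
          (1 - mom) * st[[2]]
      }
      grads <- cnn_backward(network, params, fw, Y[idx, , drop = FALSE])
      step <- step + 1L
      # bias correction folded into the step size (efficient Adam form)
      lr_t <- config$learning_rate *
        sqrt(1 - config$adam_beta2^step) / (1 - config$adam_beta1^step)
      for (nm in names(params)) {
        gmat <- grads[[nm]]
        if (is.null(gmat)) next
        wd <- if (nm %in% decay_set) config$weight_decay else 0
        adam_step_inplace(params[[nm]], adam_m[[nm]], adam_v[[nm]], gmat,
                          lr_t, config$adam_beta1, config$adam_beta2,
                          config$adam_eps, wd)
      }
    }
    history[epoch] <- epoch_loss / n
    if (verbose && (epoch %% 10 == 0 || epoch == 1))
      message(sprintf("epoch %d: loss %.5f", epoch, history[epoch]))
  }
  model <- structure(
    list(family = "cnn", network = network, params = params,
         bn_state = state, config = config, levels = levs,
         history = history),
    class = c("libsseed_cnn", "trained_classifier")
  )
  model$training_accuracy <- mean(predict_class(model, Xcal) == ycal)
  model
}

#' Predict classes with a trained CNN
#'
#' Inference-mode forward pass (batch-norm running statistics, no dropout);
#' predictions are the arg-max of the softmax outputs mapped back to labels
#' 1..3 and do not depend on how the samples are batched.
#'
#' @param model a trained CNN from \code{\link{train_cnn}}.
#' @param X spectra matrix with \code{input_length} columns.
#' @return integer label vector.
#' @export
predict_cnn <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$network$input_length)
    stop("input length does not match the network")
  probs <- cnn_probabilities(model, X)
  model$levels[max.col(probs, ties.method = "first")]
}

# softmax outputs in inference mode
cnn_probabilities <- function(model, X) {
  cnn_forward(model$network, model$params, as.matrix(X), model$config,
              training = FALSE, state = model$bn_state)$probs
}

#' @export
predict_class.libsseed_cnn <- function(model, X) predict_cnn(model, X)
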