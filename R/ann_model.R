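# Feedforward network for tabular QSPR regression: descriptor vector in,
# one property out, two hidden layers of 32 rectified linear units and a
# linear output, trained by full-batch backpropagation with
# adaptive-moment (Adam) updates on the mean squared error.

#' Configuration for the feedforward network
#'
#' @param hidden_sizes integer vector of hidden-layer widths; the study
#'   architecture is `c(32, 32)`.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum number of full-batch epochs.
#' @param patience training stops early when the best loss has not improved
#'   by more than `tol` for this many consecutive epochs.
#' @param tol minimum loss improvement counted as progress.
#' @param seed integer; fully determines weight initialization (training is
#'   full-batch, so there is no batch ordering to seed).
#' @param standardize_inputs,standardize_target z-score the inputs/target
#'   before training (the descriptor scales differ by orders of magnitude).
#' @return object of class `ann_config`.
#' @export
ann_config <- function(hidden_sizes = c(32L, 32L), learning_rate = 1e-3,
                       max_epochs = 20000L, patience = 500L, tol = 1e-10,
                       seed = 0L, standardize_inputs = TRUE,
                       standardize_target = TRUE) {
  stopifnot(length(hidden_sizes) >= 1L, all(hidden_sizes >= 1L),
            learning_rate > 0, max_epochs >= 1L, patience >= 1L, tol >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), tol = tol,
                 seed = as.integer(seed),
                 standardize_inputs = isTRUE(standardize_inputs),
                 standardize_target = isTRUE(standardize_target)),
            class = "ann_config")
}

# seed-determined scaled-uniform initialization, one weight matrix and bias
# vector per affine layer
.ann_init <- function(sizes, seed) {
  set.seed(seed)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass on standardized inputs; returns activations for backprop
.ann_forward_raw <- function(W, b, X) {
  L <- length(W)
  pre <- vector("list", L)
  act <- vector("list", L + 1L)
  act[[1L]] <- X
  for (l in seq_len(L)) {
    A <- sweep(act[[l]] %*% W[[l]], 2L, b[[l]], "+")
    pre[[l]] <- A
    act[[l + 1L]] <- if (l < L) pmax(A, 0) else A
  }
  list(pre = pre, act = act, out = drop(act[[L + 1L]]))
}

#' Loss and analytic gradients of the network by backpropagation
#'
#' Mean-squared-error loss of the network `(W, b)` on `(X, y)` together
#' with its exact gradients with respect to every weight and bias, computed
#' by reverse-mode differentiation. Exposed so the gradients can be checked
#' against finite differences.
#'
#' @param W,b lists of weight matrices and bias vectors (input layer
#'   first).
#' @param X numeric matrix of inputs (rows are samples).
#' @param y numeric response vector.
#' @return list with `loss`, `gW` and `gb` (gradients, same shapes as `W`
#'   and `b`).
#' @export
ann_gradients <- function(W, b, X, y) {
  n <- nrow(X)
  L <- length(W)
  fw <- .ann_forward_raw(W, b, X)
  resid <- fw$out - y
  loss <- mean(resid^2)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix(2 * resid / n, n, 1L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$act[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(W[[l]])) * (fw$pre[[l - 1L]] > 0)
  }
  list(loss = loss, gW = gW, gb = gb)
}

#' Train the feedforward network
#'
#' Full-batch gradient descent on the mean squared error with
#' adaptive-moment (Adam) updates. The returned model carries the weights
#' with the best observed training loss; the running-minimum loss
#' trajectory is non-increasing by construction. Identical data, config and
#' seed give bit-identical weights.
#'
#' @param X numeric matrix `n x d` of descriptors (no missing values).
#' @param y numeric response of length `n >= 2`.
#' @param config an [ann_config()].
#' @return object of class `ann_model`: weights `W`, biases `b`,
#'   standardization parameters, `loss_history` (running minimum of the
#'   standardized-scale MSE), `epochs_run` and the `config`.
#' @export
ann_train <- function(X, y, config = ann_config()) {
  stopifnot(inherits(config, "ann_config"))
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (nrow(X) < 2L || nrow(X) != length(y)) stop("need n >= 2 rows matching y")
  x_center <- if (config$standardize_inputs) colMeans(X) else rep(0, ncol(X))
  x_scale <- if (config$standardize_inputs) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  x_scale[!is.finite(x_scale) | x_scale == 0] <- 1
  y_center <- if (config$standardize_target) mean(y) else 0
  y_scale <- if (config$standardize_target) stats::sd(y) else 1
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  ys <- (y - y_center) / y_scale

  sizes <- c(ncol(X), config$hidden_sizes, 1L)
  par <- .ann_init(sizes, config$seed)
  W <- par$W; b <- par$b
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  best <- Inf; stall <- 0L
  bestW <- W; bestb <- b
  hist <- numeric(0)
  epochs <- 0L
  for (t in seq_len(config$max_epochs)) {
    g <- ann_gradients(W, b, Xs, ys)
    if (!is.finite(g$loss))
      stop("training diverged (non-finite loss); lower the learning rate")
    epochs <- t
    if (g$loss < best - config$tol) {
      best <- g$loss; stall <- 0L; bestW <- W; bestb <- b
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
    hist[t] <- best
    for (l in seq_along(W)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$gW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$gb[[l]]^2
      W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - beta1^t)) / (sqrt(vW[[l]] / (1 - beta2^t)) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - beta1^t)) / (sqrt(vb[[l]] / (1 - beta2^t)) + eps)
    }
  }
  structure(list(W = bestW, b = bestb,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 loss_history = hist, epochs_run = epochs,
                 config = config),
            class = "ann_model")
}

#' Forward pass of a trained network
#'
#' Deterministic: standardizes inputs with the training parameters, applies
#' the affine layers with rectified-linear activations and the linear
#' output, and inverse-transforms to the original response scale. A network
#' with all-zero weights returns the output bias everywhere.
#'
#' @param model an `ann_model`.
#' @param X numeric matrix (or vector for a single sample) whose column
#'   count matches the trained input layer.
#' @return numeric predictions.
#' @export
ann_forward <- function(model, X) {
  stopifnot(inherits(model, "ann_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W[[1L]]))
    stop("dimension mismatch: model expects ", nrow(model$W[[1L]]), " features")
  Xs <- sweep(sweep(X, 2L, model$x_center), 2L, model$x_scale, "/")
  .ann_forward_raw(model$W, model$b, Xs)$out * model$y_scale + model$y_center
}

#' @export
print.ann_model <- function(x, ...) {
  sizes <- c(nrow(x$W[[1L]]), vapply(x$W, ncol, 1L))
  cat("Feedforward network ", paste(sizes, collapse = " -> "),
      "; trained ", x$epochs_run, " epochs, best MSE (standardized) ",
      format(min(x$loss_history), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Regression metrics panel
#'
#' `MSE` (mean squared residual), `MAE` (mean absolute residual),
#' `RMSE = sqrt(MSE)` and `R_squared = 1 - RSS/TSS`.
#'
#' @param y_actual,y_pred numeric vectors of equal length, at least 2;
#'   `y_actual` must not be constant.
#' @return named numeric vector `MSE`, `MAE`, `RMSE`, `R_squared`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 3))
#' @export
regression_metrics <- function(y_actual, y_pred) {
  stopifnot(is.numeric(y_actual), is.numeric(y_pred),
            length(y_actual) == length(y_pred), length(y_actual) >= 2L)
  tss <- sum((y_actual - mean(y_actual))^2)
  if (tss == 0) stop("constant y_actual: R_squared undefined")
  resid <- y_actual - y_pred
  mse <- mean(resid^2)
  c(MSE = mse, MAE = mean(abs(resid)), RMSE = sqrt(mse),
    R_squared = 1 - sum(resid^2) / tss)
}
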