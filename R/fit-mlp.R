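# Single-hidden-layer perceptron trained by classic batch backpropagation:
# logistic sigmoid activations in both layers, one-hot targets, squared-error
# loss, gradient descent with momentum. Weights are initialized uniformly in
# [-0.5, 0.5] from the spec seed. With early stopping enabled (the default)
# a validation set is required; the returned weights are those with the best
# validation error seen, and training stops when the validation error fails
# to improve for 'patience' consecutive epochs.

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(X, W1, b1, W2, b2) {
  H <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
  O <- sigmoid(sweep(H %*% W2, 2, b2, "+"))
  list(H = H, O = O)
}

fit_mlp_impl <- function(control, train, validation, seed) {
  N <- as.integer(control$hidden)
  if (N < 1L) stop("MLP error: hidden-node count must be >= 1")
  if (isTRUE(control$early_stopping) &&
      (is.null(validation) || nrow(validation$values) == 0L))
    stop("MLP error: early stopping requires a non-empty validation set")
  X <- train$values
  C <- train$schema$n_classes
  T <- one_hot(train$labels, C)
  p <- ncol(X); n <- nrow(X)
  set.seed(seed)
  W1 <- matrix(stats::runif(p * N, -0.5, 0.5), p, N)
  b1 <- stats::runif(N, -0.5, 0.5)
  W2 <- matrix(stats::runif(N * C, -0.5, 0.5), N, C)
  b2 <- stats::runif(C, -0.5, 0.5)
  vW1 <- matrix(0, p, N); vb1 <- numeric(N)
  vW2 <- matrix(0, N, C); vb2 <- numeric(C)
  lr <- control$lr; mom <- control$momentum
  best <- list(err = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  stall <- 0L
  if (isTRUE(control$early_stopping)) {
    Xv <- validation$values
    Tv <- one_hot(validation$labels, C)
  }
  for (epoch in seq_len(control$epochs)) {
    fw <- mlp_forward(X, W1, b1, W2, b2)
    d2 <- (fw$O - T) * fw$O * (1 - fw$O)          # n x C
    d1 <- (d2 %*% t(W2)) * fw$H * (1 - fw$H)      # n x N
    vW2 <- mom * vW2 - lr * crossprod(fw$H, d2) / n
    vb2 <- mom * vb2 - lr * colSums(d2) / n
    vW1 <- mom * vW1 - lr * crossprod(X, d1) / n
    vb1 <- mom * vb1 - lr * colSums(d1) / n
    W2 <- W2 + vW2; b2 <- b2 + vb2
    W1 <- W1 + vW1; b1 <- b1 + vb1
    if (isTRUE(control$early_stopping)) {
      ov <- mlp_forward(Xv, W1, b1, W2, b2)$O
      verr <- mean((ov - Tv)^2)
      if (verr < best$err - 1e-12) {
        best <- list(err = verr, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= control$patience) break
      }
    }
  }
  if (isTRUE(control$early_stopping)) {
    W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, hidden = N,
       activation = "logistic")
}

#' @export
model_classify.acs_mlp <- function(object, X) {
  O <- mlp_forward(X, object$W1, object$b1, object$W2, object$b2)$O
  argmax_rows(O)
}

#' @export
print.acs_mlp <- function(x, ...) {
  cat(sprintf("MLP classifier: %d-%d-%d, %s activations\n",
              nrow(x$W1), x$hidden, x$n_classes, x$activation))
  invisible(x)
}

#' The default hidden-node model-selection grid for the MLP
#' @return Integer vector 2..13.
#' @export
mlp_hidden_grid <- function() 2:13
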