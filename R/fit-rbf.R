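# Radial basis function network trained by the classic two-step hybrid:
# (1) unsupervised placement of m Gaussian centers by seeded k-means on the
# training features, each center's spread set to its distance to the nearest
# other center (a single center uses the overall feature spread); (2)
# supervised ridge-regularized least squares from the Gaussian activations to
# one-hot targets. No bias unit: with centers at every distinct training
# point and lambda = 0 the network interpolates the targets exactly.

rbf_activations <- function(X, centers, spreads) {
  n <- nrow(X); m <- nrow(centers)
  G <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d2 <- rowSums(sweep(X, 2, centers[j, ], "-")^2)
    G[, j] <- exp(-d2 / (2 * spreads[j]^2))
  }
  G
}

fit_rbf_impl <- function(control, train, validation, seed) {
  X <- train$values
  C <- train$schema$n_classes
  if (!is.null(control$centers)) {
    centers <- as.matrix(control$centers)
  } else {
    m <- as.integer(control$m)
    ndistinct <- nrow(unique(X))
    if (m > ndistinct)
      stop(sprintf("RBF error: m = %d exceeds %d distinct training points",
                   m, ndistinct))
    set.seed(seed)
    if (m == ndistinct) {
      centers <- unique(X)
    } else {
      centers <- stats::kmeans(X, centers = m, nstart = 5L,
                               iter.max = 100L)$centers
    }
  }
  m <- nrow(centers)
  if (m == 1L) {
    spreads <- sqrt(sum(apply(X, 2, stats::var)))
    if (!is.finite(spreads) || spreads <= 0) spreads <- 1
  } else {
    D <- as.matrix(stats::dist(centers))
    diag(D) <- Inf
    spreads <- apply(D, 1, min)
    spreads[spreads <= 0] <- min(spreads[spreads > 0], 1)
  }
  G <- rbf_activations(X, centers, spreads)
  T <- one_hot(train$labels, C)
  lambda <- control$lambda
  W <- solve(crossprod(G) + diag(lambda, m), crossprod(G, T))
  list(centers = centers, spreads = spreads, W = W, m = m)
}

#' @export
model_classify.acs_rbf <- function(object, X) {
  S <- rbf_activations(X, object$centers, object$spreads) %*% object$W
  argmax_rows(S)
}

#' @export
print.acs_rbf <- function(x, ...) {
  cat(sprintf("RBF network: %d Gaussian neurons\n", x$m))
  invisible(x)
}
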