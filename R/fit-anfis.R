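# First-order Sugeno neuro-fuzzy regressor used as a classifier. The input
# space is grid-partitioned: each input gets 'mfs' Gaussian membership
# functions spread over its training range, and every combination of
# membership functions forms one fuzzy rule (mfs^p rules, capped by
# 'rule_cap'). Each rule carries a first-order consequent a_r . x + b_r; the
# network output is the firing-strength-weighted mean of the consequents.
# Training is the classic hybrid: ridge least squares for the consequent
# coefficients with premises fixed, then a normalized gradient step on the
# premise centers/spreads (numeric central differences), alternating per
# epoch with validation-based stopping. The single numeric output is
# regressed onto the integer class label; classification decodes to the
# nearest label with ties to the lower one.

anfis_weights <- function(X, centers, sigmas, combos) {
  n <- nrow(X); R <- nrow(combos)
  W <- matrix(1, n, R)
  for (j in seq_len(ncol(X))) {
    M <- exp(-outer(X[, j], centers[j, ], "-")^2 /
               rep(2 * sigmas[j, ]^2, each = n))
    W <- W * M[, combos[, j], drop = FALSE]
  }
  rs <- rowSums(W)
  rs[rs < 1e-300] <- 1e-300
  W / rs
}

anfis_design <- function(X, Wn) {
  n <- nrow(X); p <- ncol(X); R <- ncol(Wn)
  Xa <- cbind(X, 1)
  Phi <- matrix(0, n, R * (p + 1))
  for (r in seq_len(R))
    Phi[, ((r - 1) * (p + 1) + 1):(r * (p + 1))] <- Wn[, r] * Xa
  Phi
}

anfis_solve <- function(Phi, y, lambda) {
  q <- ncol(Phi)
  solve(crossprod(Phi) + diag(lambda, q), crossprod(Phi, y))
}

anfis_mse <- function(X, y, centers, sigmas, combos, theta) {
  Phi <- anfis_design(X, anfis_weights(X, centers, sigmas, combos))
  mean((drop(Phi %*% theta) - y)^2)
}

fit_anfis_impl <- function(control, train, validation, seed) {
  m <- as.integer(control$mfs)
  if (m < 2L) stop("ANFIS error: at least 2 membership functions per input")
  X <- train$values
  p <- ncol(X)
  if (m^p > control$rule_cap)
    stop(sprintf(paste("ANFIS error: %d rules exceed the cap of %d;",
                       "reduce the feature subset or 'mfs'"),
                 m^p, control$rule_cap))
  y <- as.numeric(train$labels)
  rng <- apply(X, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-8)
  centers <- t(vapply(seq_len(p),
                      function(j) seq(rng[1, j], rng[2, j], length.out = m),
                      numeric(m)))
  sigmas <- matrix(rep(span / (2 * (m - 1)), m), p, m)
  combos <- as.matrix(expand.grid(rep(list(seq_len(m)), p)))
  lambda <- control$lambda
  theta <- anfis_solve(anfis_design(X, anfis_weights(X, centers, sigmas,
                                                     combos)), y, lambda)
  has_val <- !is.null(validation) && nrow(validation$values) > 0L
  if (has_val) {
    Xv <- validation$values
    yv <- as.numeric(validation$labels)
  }
  score <- function(ct, sg, th)
    if (has_val) anfis_mse(Xv, yv, ct, sg, combos, th)
    else anfis_mse(X, y, ct, sg, combos, th)
  best <- list(err = score(centers, sigmas, theta), centers = centers,
               sigmas = sigmas, theta = theta)
  stall <- 0L
  h <- 1e-4 * span
  for (epoch in seq_len(control$epochs)) {
    # numeric gradient of the training MSE w.r.t. premise parameters,
    # consequents held fixed
    gc <- matrix(0, p, m); gs <- matrix(0, p, m)
    for (j in seq_len(p)) for (l in seq_len(m)) {
      cp <- centers; cm <- centers
      cp[j, l] <- cp[j, l] + h[j]; cm[j, l] <- cm[j, l] - h[j]
      gc[j, l] <- (anfis_mse(X, y, cp, sigmas, combos, theta) -
                   anfis_mse(X, y, cm, sigmas, combos, theta)) / (2 * h[j])
      sp <- sigmas; sm <- sigmas
      sp[j, l] <- sp[j, l] + h[j]; sm[j, l] <- max(sm[j, l] - h[j], 1e-8)
      gs[j, l] <- (anfis_mse(X, y, centers, sp, combos, theta) -
                   anfis_mse(X, y, centers, sm, combos, theta)) / (2 * h[j])
    }
    gmax <- max(abs(gc), abs(gs))
    if (gmax > 0) {
      step <- control$lr / gmax
      centers <- centers - step * gc * span
      sigmas <- pmax(sigmas - step * gs * span, 1e-6 * span)
    }
    theta <- anfis_solve(anfis_design(X, anfis_weights(X, centers, sigmas,
                                                       combos)), y, lambda)
    err <- score(centers, sigmas, theta)
    if (err < best$err - 1e-12) {
      best <- list(err = err, centers = centers, sigmas = sigmas,
                   theta = theta)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }
  list(centers = best$centers, sigmas = best$sigmas, theta = best$theta,
       combos = combos, mfs = m)
}

anfis_output <- function(object, X) {
  Wn <- anfis_weights(X, object$centers, object$sigmas, object$combos)
  drop(anfis_design(X, Wn) %*% object$theta)
}

#' @export
model_classify.acs_anfis <- function(object, X) {
  yhat <- anfis_output(object, X)
  pmin(pmax(ceiling(yhat - 0.5), 1), object$n_classes)
}

#' @export
print.acs_anfis <- function(x, ...) {
  cat(sprintf("Sugeno neuro-fuzzy classifier: %d MFs/input, %d rules\n",
              x$mfs, nrow(x$combos)))
  invisible(x)
}
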