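# Naive Bayes with mixed feature scales: empirical class priors, additively
# smoothed categorical conditionals (count + alpha) / (n_c + alpha * |codes|),
# and per-class Gaussians with a variance floor for ratio features. The
# posterior argmax is computed in log space.

fit_nb_impl <- function(control, train, validation, seed) {
  alpha <- control$alpha
  var_floor <- control$var_floor
  if (alpha < 0) stop("Naive Bayes error: smoothing alpha must be >= 0")
  if (var_floor <= 0) stop("Naive Bayes error: variance floor must be > 0")
  C <- train$schema$n_classes
  y <- train$labels
  nc <- tabulate(y, C)
  priors <- nc / length(y)
  scales <- schema_scales(train$schema)
  tables <- vector("list", ncol(train$values))
  for (j in seq_len(ncol(train$values))) {
    f <- train$schema$features[[j]]
    v <- train$values[, j]
    if (f$scale == "ratio") {
      m <- s2 <- numeric(C)
      for (c in seq_len(C)) {
        vc <- v[y == c]
        if (length(vc)) {
          m[c] <- mean(vc)
          s2[c] <- max(sum((vc - m[c])^2) / length(vc), var_floor)
        } else {
          s2[c] <- var_floor
        }
      }
      tables[[j]] <- list(type = "ratio", mean = m, var = s2)
    } else {
      K <- length(f$codes)
      probs <- matrix(0, C, K, dimnames = list(NULL, f$codes))
      for (c in seq_len(C)) {
        cnt <- vapply(f$codes, function(cd) sum(v == cd & y == c), numeric(1))
        denom <- nc[c] + alpha * K
        probs[c, ] <- if (denom > 0) (cnt + alpha) / denom else rep(1 / K, K)
      }
      tables[[j]] <- list(type = "categorical", codes = f$codes, probs = probs)
    }
  }
  list(priors = priors, tables = tables, alpha = alpha)
}

#' @export
model_classify.acs_naive_bayes <- function(object, X) {
  C <- object$n_classes
  n <- nrow(X)
  logp <- matrix(rep(log(object$priors), each = n), n, C)
  for (j in seq_len(ncol(X))) {
    tb <- object$tables[[j]]
    if (tb$type == "ratio") {
      for (c in seq_len(C))
        logp[, c] <- logp[, c] +
          stats::dnorm(X[, j], tb$mean[c], sqrt(tb$var[c]), log = TRUE)
    } else {
      idx <- match(X[, j], tb$codes)
      for (c in seq_len(C)) {
        pr <- ifelse(is.na(idx), 0, tb$probs[c, pmax(idx, 1L)])
        logp[, c] <- logp[, c] + log(pr)
      }
    }
  }
  argmax_rows(logp)
}

#' @export
print.acs_naive_bayes <- function(x, ...) {
  cat(sprintf("Naive Bayes classifier (alpha = %g), priors: %s\n", x$alpha,
              paste(sprintf("%.3f", x$priors), collapse = ", ")))
  invisible(x)
}
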