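# GLM classifier: one weighted-least-squares regression per class against
# one-hot targets, fitted by iteratively reweighted least squares with the
# link/distribution pairs normal (identity), inverse Gaussian (1/mu^2),
# Poisson (log) and gamma (1/mu). Classification is the argmax of the C
# fitted means. For the normal/identity pair IRLS reduces to plain least
# squares in one step.

glm_family <- function(distribution) {
  switch(distribution,
         normal = stats::gaussian(),
         inverse_gaussian = stats::inverse.gaussian(),
         poisson = stats::poisson(),
         gamma = stats::Gamma(link = "inverse"),
         stop(sprintf("unknown GLM distribution '%s'", distribution)))
}

# IRLS on a fixed design. One-hot targets make raw means hit the boundary of
# the log / reciprocal links, so fitted means are clamped to
# [1e-6, 1 - 1e-6] before every link evaluation.
irls_fit <- function(X, y, fam, maxit = 50L, tol = 1e-10,
                     clamp = c(1e-6, 1 - 1e-6)) {
  clamp_mu <- function(mu) pmin(pmax(mu, clamp[1]), clamp[2])
  mu <- clamp_mu((y + 0.5) / 2)
  eta <- fam$linkfun(mu)
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    me <- fam$mu.eta(eta)
    w <- me^2 / fam$variance(mu)
    # boundary-clamped observations can drive their weights to ~0 for the
    # reciprocal links; floor them so the weighted design keeps full rank
    w <- pmax(w, 1e-8 * max(w))
    z <- eta + (y - mu) / me
    sw <- sqrt(w)
    b_new <- qr.coef(qr(X * sw), z * sw)
    if (anyNA(b_new))
      stop("GLM error: weighted design became singular during IRLS")
    mu <- clamp_mu(fam$linkinv(drop(X %*% b_new)))
    eta <- fam$linkfun(mu)
    done <- max(abs(b_new - b)) < tol * (1 + max(abs(b_new)))
    b <- b_new
    if (done) break
  }
  b
}

fit_glm_impl <- function(control, train, validation, seed) {
  dist <- match.arg(control$distribution,
                    c("normal", "inverse_gaussian", "poisson", "gamma"))
  encoding <- match.arg(control$encoding, c("one_vs_rest", "label"))
  X <- cbind(`(Intercept)` = 1, train$values)
  dup <- duplicated(t(X))
  Xd <- X[, !dup, drop = FALSE]
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qx$pivot[(qx$rank + 1L):ncol(Xd)]]
    stop(sprintf("GLM error: singular design; collinear feature(s): %s",
                 paste(bad, collapse = ", ")))
  }
  fam <- glm_family(dist)
  C <- train$schema$n_classes
  if (encoding == "one_vs_rest") {
    targets <- one_hot(train$labels, C)
  } else {
    targets <- matrix(as.numeric(train$labels), ncol = 1)
  }
  B <- matrix(0, ncol(X), ncol(targets),
              dimnames = list(colnames(X), NULL))
  for (c in seq_len(ncol(targets))) {
    y <- targets[, c]
    if (dist == "normal") {
      B[, c] <- qr.coef(qr(X), y)
    } else if (encoding == "label") {
      # positive integer targets: no boundary clamping needed beyond floor
      B[, c] <- irls_fit(X, y, fam, clamp = c(1e-6, C + 1))
    } else {
      B[, c] <- irls_fit(X, y, fam)
    }
  }
  list(coefficients = B, distribution = dist,
       link = fam$link, encoding = encoding)
}

#' @export
model_classify.acs_glm <- function(object, X) {
  fam <- glm_family(object$distribution)
  eta <- cbind(1, X) %*% object$coefficients
  mu <- fam$linkinv(eta)
  if (object$encoding == "label")
    return(pmin(pmax(ceiling(drop(mu) - 0.5), 1L), object$n_classes))
  argmax_rows(mu)
}

#' @export
coef.acs_glm <- function(object, ...) object$coefficients

#' @export
print.acs_glm <- function(x, ...) {
  cat(sprintf("GLM classifier (%s distribution, link %s, %s encoding)\n",
              x$distribution, x$link, x$encoding))
  invisible(x)
}
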