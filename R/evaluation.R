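#' Confusion matrices and probability metrics
#'
#' A confusion matrix counts test samples by actual class (rows) and
#' predicted class (columns). Two conditional-probability views are derived
#' from it: the accuracy probability matrix (APM), whose entry (i, j) is
#' p(predicted j | actual i), obtained by dividing each row by its row sum;
#' and the correctness probability matrix (CPM), whose entry (i, j) is
#' p(actual i | predicted j), the Bayes inversion of the APM under class
#' priors p(c):
#' \deqn{CPM_{ij} = \frac{APM_{ij}\, p(c_i)}{\sum_k APM_{kj}\, p(c_k)}.}
#' Under the empirical priors of the same confusion matrix this reduces to
#' column normalization of the counts. Zero-support rows (APM) or columns
#' (CPM) are set to zero and flagged rather than returned as NaN.
#'
#' @param actual,predicted integer label vectors of equal length, values in
#'   \code{1..C}.
#' @param C number of classes.
#' @return \code{build_cm}: an \code{"acs_cm"} (integer C-by-C matrix with a
#'   \code{usable} attribute). \code{compute_apm}/\code{compute_cpm}: an
#'   \code{"acs_probmatrix"} with attributes \code{orientation} ("APM" or
#'   "CPM") and \code{flagged} (indices of zero-support rows/columns).
#' @export
build_cm <- function(actual, predicted, C) {
  if (length(actual) != length(predicted))
    stop("confusion matrix error: label vectors differ in length")
  actual <- as.integer(actual); predicted <- as.integer(predicted)
  if (length(actual) && (min(actual, predicted) < 1L ||
                         max(actual, predicted) > C))
    stop("confusion matrix error: labels outside 1..C")
  cm <- matrix(0L, C, C)
  for (i in seq_along(actual))
    cm[actual[i], predicted[i]] <- cm[actual[i], predicted[i]] + 1L
  structure(cm, usable = length(actual) > 0L, class = c("acs_cm", "matrix"))
}

#' Overall accuracy of a confusion matrix
#'
#' The trace of the matrix divided by its grand total: the fraction of test
#' samples whose predicted class equals the actual class. Identically equal
#' to the prior-weighted APM diagonal,
#' \eqn{\sum_i p(c_i)\, APM_{ii}} with empirical priors.
#'
#' @param cm a confusion matrix (counts, rows = actual).
#' @return Accuracy as a fraction in \code{[0, 1]}.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("accuracy error: empty confusion matrix")
  sum(diag(as.matrix(cm))) / total
}

#' @rdname build_cm
#' @param cm a confusion matrix.
#' @export
compute_apm <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  apm <- cm / ifelse(rs > 0, rs, 1)
  apm[rs == 0, ] <- 0
  structure(apm, orientation = "APM", flagged = which(rs == 0),
            class = c("acs_probmatrix", "matrix"))
}

#' @rdname build_cm
#' @param apm an APM probability matrix from [compute_apm()].
#' @param priors class prior probabilities (simplex vector), e.g. from
#'   [empirical_priors()].
#' @export
compute_cpm <- function(apm, priors) {
  apm <- as.matrix(apm)
  C <- nrow(apm)
  if (length(priors) != C || abs(sum(priors) - 1) > 1e-9 || any(priors < 0))
    stop("CPM error: priors must be a non-negative simplex vector of length C")
  joint <- apm * priors          # recycles priors down rows: joint_ij = apm_ij * p_i
  cs <- colSums(joint)
  cpm <- sweep(joint, 2, ifelse(cs > 0, cs, 1), "/")
  cpm[, cs == 0] <- 0
  structure(cpm, orientation = "CPM", flagged = which(cs == 0),
            class = c("acs_probmatrix", "matrix"))
}

#' Empirical class priors from counts
#'
#' @param counts non-negative class counts (e.g. row sums of a confusion
#'   matrix, or the class frequencies of the full dataset).
#' @return Normalized proportions summing to 1.
#' @export
empirical_priors <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("priors error: zero total count")
  as.numeric(counts) / total
}

#' @export
print.acs_probmatrix <- function(x, digits = 2, ...) {
  cat(sprintf("%s (%s-stochastic)\n", attr(x, "orientation"),
              if (attr(x, "orientation") == "APM") "row" else "column"))
  print(round(unclass(x), digits))
  fl <- attr(x, "flagged")
  if (length(fl)) cat("  zero-support:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Element-wise mean and standard deviation across repetitions
#'
#' Aggregates a list of same-shaped matrices (e.g. per-repetition APMs) or a
#' numeric vector (e.g. per-repetition accuracies) as element-wise mean and
#' sample standard deviation (n - 1 denominator). A single repetition yields
#' a zero standard deviation with a flag.
#'
#' @param runs non-empty list of equal-dimension numeric matrices, or a
#'   numeric vector.
#' @return A list with components \code{mean}, \code{sd}, \code{n} and
#'   \code{flagged_single}.
#' @export
aggregate_runs <- function(runs) {
  if (is.numeric(runs)) runs <- as.list(runs)
  if (!length(runs)) stop("aggregation error: no runs")
  dims <- dim(as.matrix(runs[[1]]))
  arr <- vapply(runs, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == dims)) stop("aggregation error: shape mismatch")
    as.numeric(m)
  }, numeric(prod(dims)))
  arr <- matrix(arr, nrow = prod(dims))   # elements x runs
  mu <- rowMeans(arr)
  sd <- if (ncol(arr) > 1) apply(arr, 1, stats::sd) else rep(0, nrow(arr))
  shape_back <- function(v) if (all(dims == c(1, 1))) v[1] else
    matrix(v, dims[1], dims[2])
  list(mean = shape_back(mu), sd = shape_back(sd), n = length(runs),
       flagged_single = length(runs) == 1L)
}
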