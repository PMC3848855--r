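# Small schema / dataset builders shared across the suite. All fixtures are
# constructed in code; nothing is read from disk.

ratio_schema <- function(p, C = 2L) {
  acs_schema(lapply(seq_len(p), function(j)
    list(label = j, name = paste0("x", j), scale = "ratio")),
    n_classes = C, class_names = paste0("c", seq_len(C)))
}

# p categorical features, each with the given code vector
nominal_schema <- function(p, codes = c(1, 2), C = 2L) {
  acs_schema(lapply(seq_len(p), function(j)
    list(label = j, name = paste0("f", j), scale = "nominal", codes = codes)),
    n_classes = C, class_names = paste0("c", seq_len(C)))
}

# 1-D two-class ratio dataset
dataset_1d <- function(x, y, C = 2L) {
  acs_dataset(matrix(as.numeric(x), ncol = 1), y, ratio_schema(1, C))
}

# the worked-example confusion matrix (rows = actual, cols = predicted)
worked_example_cm <- function() {
  matrix(c(1, 0, 1, 11,
           0, 49, 1, 5,
           0, 6, 12, 11,
           3, 0, 7, 95), 4, 4, byrow = TRUE)
}

# label vectors realizing a count matrix
labels_from_cm <- function(cm) {
  actual <- integer(0); predicted <- integer(0)
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    actual <- c(actual, rep(i, cm[i, j]))
    predicted <- c(predicted, rep(j, cm[i, j]))
  }
  list(actual = actual, predicted = predicted)
}

one_hot_test <- function(y, C) {
  T <- matrix(0, length(y), C)
  T[cbind(seq_along(y), y)] <- 1
  T
}

random_cm <- function(C = 4, lambda = 20) {
  matrix(stats::rpois(C * C, lambda), C, C)
}

# brute-force k-NN oracle replicating the documented tie-break rules via a
# full distance matrix and a complete sort
knn_oracle <- function(Xtr, ytr, Xte, k, C) {
  apply(Xte, 1, function(x) {
    d <- colSums((t(Xtr) - x)^2)
    ord <- order(d, seq_along(d))
    nb <- ord[seq_len(k)]
    votes <- tabulate(ytr[nb], C)
    top <- which(votes == max(votes))
    if (length(top) > 1) {
      mean_d <- vapply(top, function(c) mean(d[nb][ytr[nb] == c]), numeric(1))
      top <- top[order(mean_d, top)]
    }
    top[1]
  })
}

# a small mixed-signal dataset: feature 1 determines the class, the rest are
# uniform categorical noise
planted_dataset <- function(n = 60, p_noise = 2, seed = 1, C = 2L) {
  set.seed(seed)
  y <- rep_len(seq_len(C), n)
  vals <- cbind(y, matrix(sample(1:2, n * p_noise, replace = TRUE), n))
  sch <- nominal_schema(1 + p_noise, codes = seq_len(max(2, C)), C = C)
  acs_dataset(vals, y, sch, check = FALSE)
}

# zero-signal generator config on a tiny schema with the study's priors
zero_signal_config <- function(n = 600) {
  sch <- acs_schema(list(
    list(label = 1, name = "n1", scale = "nominal", codes = c(1, 2)),
    list(label = 2, name = "n2", scale = "ordinal", codes = c(1, 2, 3)),
    list(label = 3, name = "r1", scale = "ratio")), n_classes = 4,
    class_names = c("STEMI", "NSTEMI", "UA", "Other"))
  generator_config(n = n, class_probs = c(0.2769, 0.1582, 0.5155, 0.0494),
                   schema = sch, informative = integer(0))
}
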