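# k-nearest-neighbour classifier. Lazy learner: the model stores the coded /
# normalized training matrix and the neighbour count k; prediction finds the
# k smallest Euclidean distances and takes the plurality class. Tie-breaks
# are deterministic: tied vote counts go to the class with the smaller mean
# neighbour distance, then to the lower class index; distance ties at the
# k-th neighbour resolve by training-row order. The distance search runs in
# compiled code (src/knn.cpp).

fit_knn_impl <- function(control, train, validation, seed) {
  k <- as.integer(control$k)
  if (k > nrow(train$values))
    stop(sprintf("k-NN error: k = %d exceeds training size %d", k,
                 nrow(train$values)))
  list(X = train$values, y = train$labels, k = k)
}

#' @export
model_classify.acs_knn <- function(object, X) {
  knn_predict_cpp(object$X, object$y, X, object$k, object$n_classes)
}

#' @export
print.acs_knn <- function(x, ...) {
  cat(sprintf("k-NN classifier: k = %d, %d stored training samples\n",
              x$k, nrow(x$X)))
  invisible(x)
}
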