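#' Classifier specifications
#'
#' A \code{classifier_spec} names one of the eight supported learners and
#' carries its hyperparameters and (for stochastic trainers) a seed. All
#' learners share the same contract: [acs_fit()] turns a spec plus training
#' data into a fitted \code{"acs_model"}, and [predict()] maps feature rows
#' to hard class labels in \code{1..n_classes}.
#'
#' Supported kinds and their hyperparameters (defaults in parentheses):
#' \describe{
#'   \item{\code{glm}}{\code{distribution} one of \code{"normal"},
#'     \code{"inverse_gaussian"}, \code{"poisson"}, \code{"gamma"}
#'     (\code{"normal"}); \code{encoding} \code{"one_vs_rest"} (one GLM per
#'     class on one-hot targets, argmax of fitted means) or \code{"label"}
#'     (regress the integer label, round to the nearest class).}
#'   \item{\code{knn}}{\code{k} odd positive neighbour count (7).}
#'   \item{\code{naive_bayes}}{\code{alpha} additive smoothing for
#'     categorical conditionals (1); \code{var_floor} minimum per-class
#'     Gaussian variance for ratio features (1e-9).}
#'   \item{\code{id3}}{\code{min_split} smallest node that may be split (2);
#'     \code{max_depth} (Inf).}
#'   \item{\code{bagging_id3}}{\code{B} bootstrap replicates (50);
#'     \code{resample} \code{"bootstrap"} or \code{"identity"} (test hook);
#'     plus the \code{id3} controls.}
#'   \item{\code{mlp}}{\code{hidden} hidden-node count (9); \code{lr}
#'     learning rate (0.5); \code{momentum} (0.9); \code{epochs} (500);
#'     \code{patience} early-stopping window (30); \code{early_stopping}
#'     (TRUE, requires a validation set).}
#'   \item{\code{rbf}}{\code{m} radial neurons (7); \code{lambda} ridge
#'     constant for the output weights (1e-8); \code{centers} optional fixed
#'     center matrix overriding k-means.}
#'   \item{\code{anfis}}{\code{mfs} Gaussian membership functions per input
#'     (2); \code{epochs} (30); \code{patience} (5); \code{lr} premise
#'     learning rate (0.02); \code{rule_cap} maximum number of fuzzy rules
#'     (512); \code{lambda} ridge constant for the consequents (1e-8).}
#' }
#'
#' @param what one of \code{"glm"}, \code{"knn"}, \code{"naive_bayes"},
#'   \code{"id3"}, \code{"bagging_id3"}, \code{"mlp"}, \code{"rbf"},
#'   \code{"anfis"}. (The argument is deliberately not named \code{kind}:
#'   hyperparameters such as \code{k} arrive through \code{...} and must not
#'   partially match the first formal.)
#' @param ... hyperparameters overriding the kind's defaults (see Details).
#' @param seed integer seed used by stochastic trainers.
#' @return A \code{"classifier_spec"}.
#' @export
classifier_spec <- function(what, ..., seed = 1L) {
  kind <- match.arg(what, c("glm", "knn", "naive_bayes", "id3", "bagging_id3",
                            "mlp", "rbf", "anfis"))
  defaults <- switch(kind,
    glm = list(distribution = "normal", encoding = "one_vs_rest"),
    knn = list(k = 7L),
    naive_bayes = list(alpha = 1, var_floor = 1e-9),
    id3 = list(min_split = 2L, max_depth = Inf),
    bagging_id3 = list(B = 50L, resample = "bootstrap", min_split = 2L,
                       max_depth = Inf),
    mlp = list(hidden = 9L, lr = 0.5, momentum = 0.9, epochs = 500L,
               patience = 30L, early_stopping = TRUE),
    rbf = list(m = 7L, lambda = 1e-8, centers = NULL),
    anfis = list(mfs = 2L, epochs = 30L, patience = 5L, lr = 0.02,
                 rule_cap = 512L, lambda = 1e-8))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown hyperparameter(s) for kind '%s': %s", kind,
                 paste(unknown, collapse = ", ")))
  control <- utils::modifyList(defaults, override)
  if (kind == "knn") {
    k <- control$k
    if (k < 1 || k %% 2 == 0)
      stop("k-NN requires an odd positive neighbour count k")
  }
  structure(list(kind = kind, control = control, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  ctl <- x$control[!vapply(x$control, is.null, logical(1))]
  cat(sprintf("classifier spec '%s' (%s)\n", x$kind,
              paste(sprintf("%s=%s", names(ctl),
                            vapply(ctl, function(v) paste(format(v), collapse = "/"),
                                   character(1))), collapse = ", ")))
  invisible(x)
}

#' Fit a classifier to an ACS dataset
#'
#' The single fitting entry point for all eight learners. Validation data is
#' required by the kinds that tune or stop on a held-out set (\code{mlp} with
#' early stopping, \code{anfis}); the remaining kinds ignore it.
#'
#' @param spec a [classifier_spec()].
#' @param train an \code{"acs_dataset"} (feature values are used as given;
#'   normalize ratio features beforehand if desired).
#' @param validation optional \code{"acs_dataset"} with the same feature set.
#' @return A fitted model of class \code{c("acs_<kind>", "acs_model")}.
#' @seealso [predict.acs_model()]
#' @examples
#' gen <- generate_acs(default_acs_config(n = 120), seed = 1)
#' model <- acs_fit(classifier_spec("naive_bayes"), gen$dataset)
#' table(predict(model, gen$dataset), gen$dataset$labels)
#' @export
acs_fit <- function(spec, train, validation = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(train, "acs_dataset"))
  if (nrow(train$values) == 0L) stop("training set is empty")
  if (!is.null(validation) && ncol(validation$values) != ncol(train$values))
    stop("validation feature width does not match training width")
  fitter <- switch(spec$kind,
    glm = fit_glm_impl, knn = fit_knn_impl, naive_bayes = fit_nb_impl,
    id3 = fit_id3_impl, bagging_id3 = fit_bagging_impl, mlp = fit_mlp_impl,
    rbf = fit_rbf_impl, anfis = fit_anfis_impl)
  model <- fitter(spec$control, train, validation, spec$seed)
  model$kind <- spec$kind
  model$n_classes <- train$schema$n_classes
  model$p <- ncol(train$values)
  model$feature_names <- colnames(train$values)
  class(model) <- c(paste0("acs_", spec$kind), "acs_model")
  model
}

#' Predict class labels from a fitted model
#'
#' @param object an \code{"acs_model"} from [acs_fit()].
#' @param newdata an \code{"acs_dataset"} or a numeric matrix whose columns
#'   match the training feature width.
#' @param ... unused.
#' @return Integer labels in \code{1..n_classes}, one per row (an empty input
#'   yields an empty vector). Predictions are deterministic given the model.
#' @export
predict.acs_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "acs_dataset")) newdata$values else as.matrix(newdata)
  if (length(X) == 0L || nrow(X) == 0L) return(integer(0))
  storage.mode(X) <- "double"
  if (ncol(X) != object$p)
    stop(sprintf("feature width mismatch: model expects %d columns, got %d",
                 object$p, ncol(X)))
  as.integer(model_classify(object, X))
}

# internal per-kind prediction dispatch on the fitted object
model_classify <- function(object, X) UseMethod("model_classify")

#' @export
print.acs_model <- function(x, ...) {
  cat(sprintf("fitted '%s' classifier: %d features, %d classes\n",
              x$kind, x$p, x$n_classes))
  invisible(x)
}

# argmax over columns with ties to the lowest class index
argmax_rows <- function(S) max.col(S, ties.method = "first")

# majority class of an integer label vector; ties to the lowest class index
majority_class <- function(y, C) which.max(tabulate(y, C))

one_hot <- function(y, C) {
  T <- matrix(0, length(y), C)
  T[cbind(seq_along(y), y)] <- 1
  T
}
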