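#' Data-splitting schemes for repeated random sub-sampling
#'
#' Two-way splits (training/test, default fractions 0.7/0.3) estimate test
#' error; three-way splits (training/validation/test, default 0.6/0.2/0.2)
#' additionally reserve a validation part for hyperparameter tuning and
#' early stopping. Splits are stratified by class by default so that the
#' rare "Other" class stays represented in every part.
#'
#' @param mode \code{"two_way"} or \code{"three_way"}.
#' @param fractions part fractions summing to 1; \code{NULL} picks the mode
#'   default.
#' @param reps number of repetitions for [repeated_evaluation()].
#' @param stratified stratify splits by class (default TRUE).
#' @return A \code{"split_scheme"}.
#' @export
split_scheme <- function(mode = c("two_way", "three_way"), fractions = NULL,
                         reps = 1000L, stratified = TRUE) {
  mode <- match.arg(mode)
  if (is.null(fractions))
    fractions <- if (mode == "two_way") c(0.7, 0.3) else c(0.6, 0.2, 0.2)
  nparts <- if (mode == "two_way") 2L else 3L
  if (length(fractions) != nparts || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("split error: fractions must be positive and sum to 1")
  reps <- as.integer(reps)
  if (reps < 1L) stop("split error: reps must be >= 1")
  structure(list(mode = mode, fractions = fractions, reps = reps,
                 stratified = isTRUE(stratified),
                 part_names = if (mode == "two_way") c("train", "test")
                              else c("train", "validation", "test")),
            class = "split_scheme")
}

# largest-remainder apportionment of 'total' seats by 'quotas'
apportion <- function(quotas, total) {
  base <- floor(quotas)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quotas - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a dataset into disjoint, exhaustive parts
#'
#' Part sizes follow largest-remainder apportionment of the scheme fractions
#' over the total n; under stratification the class counts within each part
#' are then apportioned the same way, preserving the class proportions to
#' within one sample per class per part. The assignment is deterministic
#' given the seed.
#'
#' @param data an \code{"acs_dataset"}.
#' @param scheme a [split_scheme()].
#' @param seed integer seed.
#' @return A named list of disjoint row-index vectors covering
#'   \code{1..nrow} (\code{train}/\code{test} or
#'   \code{train}/\code{validation}/\code{test}).
#' @export
make_split <- function(data, scheme, seed) {
  n <- nrow(data$values)
  J <- length(scheme$fractions)
  part_totals <- apportion(n * scheme$fractions, n)
  set.seed(as.integer(seed))
  if (!scheme$stratified) {
    perm <- sample.int(n)
    ends <- cumsum(part_totals)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    parts <- lapply(seq_len(J), function(j) sort(perm[starts[j]:ends[j]]))
  } else {
    C <- data$schema$n_classes
    counts <- tabulate(data$labels, C)
    alloc <- matrix(0L, C, J)
    left <- counts
    for (j in seq_len(J - 1L)) {
      quotas <- counts * scheme$fractions[j]
      a <- apportion(quotas, part_totals[j])
      a <- pmin(a, left)
      short <- part_totals[j] - sum(a)
      while (short > 0) {              # rare: borrow from classes with slack
        room <- which(left - a > 0)
        a[room[1L]] <- a[room[1L]] + 1L
        short <- short - 1L
      }
      alloc[, j] <- a
      left <- left - a
    }
    alloc[, J] <- left
    if (any(alloc < 1L))
      stop("split error: a class is too small to stratify into every part")
    parts <- rep(list(integer(0)), J)
    for (c in seq_len(C)) {
      rows <- which(data$labels == c)
      rows <- rows[sample.int(length(rows))]
      ends <- cumsum(alloc[c, ])
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      for (j in seq_len(J))
        parts[[j]] <- c(parts[[j]], rows[starts[j]:ends[j]])
    }
    parts <- lapply(parts, sort)
  }
  names(parts) <- scheme$part_names
  parts
}

# kinds whose evaluation protocol reserves a validation part
three_way_kinds <- c("mlp", "rbf", "anfis", "bagging_id3")

#' Repeated random sub-sampling evaluation of a classifier
#'
#' Runs \code{scheme$reps} independent repetitions: split the data, fit the
#' ratio-feature normalizer (per the \code{normalization} scope), train the
#' classifier on the training part (passing the validation part to kinds
#' that use one), and record the test-set confusion matrix. Per-repetition
#' seeds are drawn once from the master seed, so the whole run list is
#' reproducible and repetitions never share a seed.
#'
#' @param spec a [classifier_spec()].
#' @param data an \code{"acs_dataset"}.
#' @param scheme a [split_scheme()]; kinds that tune or stop on a validation
#'   set (mlp, rbf, anfis, bagging_id3) expect three-way mode — a two-way
#'   scheme triggers a warning (or an error when \code{strict}).
#' @param seed master integer seed.
#' @param normalization \code{"split"} (fit min-max stats on the training
#'   part only; default), \code{"global"} (fit once on the full dataset) or
#'   \code{"none"}.
#' @param strict escalate the scheme-mismatch warning to an error.
#' @return An \code{"acs_eval"} object: list of per-repetition runs (each
#'   with \code{rep}, \code{seed}, \code{cm}, \code{accuracy}) plus metadata.
#' @export
repeated_evaluation <- function(spec, data, scheme, seed,
                                normalization = c("split", "global", "none"),
                                strict = FALSE) {
  normalization <- match.arg(normalization)
  if (spec$kind %in% three_way_kinds && scheme$mode != "three_way") {
    msg <- sprintf("classifier '%s' is normally evaluated with a three-way split",
                   spec$kind)
    if (strict) stop(msg) else warning(msg)
  }
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * scheme$reps),
                  ncol = 2L)
  C <- data$schema$n_classes
  if (normalization == "global")
    data <- apply_normalizer(data, fit_normalizer(data))
  runs <- vector("list", scheme$reps)
  for (r in seq_len(scheme$reps)) {
    parts <- make_split(data, scheme, seeds[r, 1L])
    d <- data
    if (normalization == "split") {
      stats <- fit_normalizer(subset_acs(d, rows = parts$train))
      d <- apply_normalizer(d, stats)
    }
    train <- subset_acs(d, rows = parts$train)
    val <- if (!is.null(parts$validation))
      subset_acs(d, rows = parts$validation) else NULL
    rspec <- spec
    rspec$seed <- seeds[r, 2L]
    model <- acs_fit(rspec, train, val)
    test <- subset_acs(d, rows = parts$test)
    pred <- predict(model, test)
    cm <- build_cm(test$labels, pred, C)
    runs[[r]] <- list(rep = r, seed = seeds[r, 1L], cm = cm,
                      accuracy = overall_accuracy(cm))
  }
  structure(list(runs = runs, spec = spec, scheme = scheme,
                 seed = as.integer(seed), normalization = normalization),
            class = "acs_eval")
}

#' @export
print.acs_eval <- function(x, ...) {
  acc <- vapply(x$runs, `[[`, numeric(1), "accuracy")
  ag <- aggregate_runs(acc)
  cat(sprintf("%s, %d x %s evaluation: accuracy %.4f +/- %.4f\n",
              x$spec$kind, length(x$runs), x$scheme$mode, ag$mean, ag$sd))
  invisible(x)
}

#' Summarize an evaluation: aggregate accuracy, APM and CPM
#'
#' Each repetition's APM (and, from it, CPM) is computed from that
#' repetition's confusion matrix and the matrices are then aggregated
#' element-wise as mean and sample standard deviation; this per-run mode
#' keeps the mean APM row-stochastic and the mean CPM column-stochastic.
#' Alternatively \code{cpm_mode = "pooled"} applies the Bayes inversion once
#' to the mean APM.
#'
#' @param object an \code{"acs_eval"}.
#' @param priors class priors for the CPM; default the empirical priors of
#'   the pooled test confusion matrices.
#' @param cpm_mode \code{"per_run"} (default) or \code{"pooled"}.
#' @param ... unused.
#' @return A list with \code{accuracy} (mean/sd), \code{apm} and \code{cpm}
#'   (each mean/sd matrices), and \code{pooled_cm}.
#' @export
summary.acs_eval <- function(object, priors = NULL,
                             cpm_mode = c("per_run", "pooled"), ...) {
  cpm_mode <- match.arg(cpm_mode)
  acc <- aggregate_runs(vapply(object$runs, `[[`, numeric(1), "accuracy"))
  apms <- lapply(object$runs, function(r) compute_apm(r$cm))
  apm <- aggregate_runs(lapply(apms, unclass))
  pooled <- Reduce(`+`, lapply(object$runs, function(r) unclass(r$cm)))
  if (is.null(priors)) priors <- empirical_priors(rowSums(pooled))
  if (cpm_mode == "per_run") {
    cpms <- lapply(apms, function(a) unclass(compute_cpm(a, priors)))
    cpm <- aggregate_runs(cpms)
  } else {
    cpm <- list(mean = unclass(compute_cpm(apm$mean, priors)), sd = NULL,
                n = apm$n, flagged_single = apm$flagged_single)
  }
  out <- list(kind = object$spec$kind, accuracy = acc, apm = apm, cpm = cpm,
              priors = priors, pooled_cm = pooled, reps = length(object$runs))
  class(out) <- "summary.acs_eval"
  out
}

#' @export
print.summary.acs_eval <- function(x, digits = 2, ...) {
  cat(sprintf("%s over %d repetitions\n", x$kind, x$reps))
  cat(sprintf("  accuracy: %.2f +/- %.2f %%\n", 100 * x$accuracy$mean,
              100 * x$accuracy$sd))
  cat("  mean APM (%):\n")
  print(round(100 * x$apm$mean, digits))
  invisible(x)
}

#' Grid model selection on the validation part
#'
#' For every grid value of one hyperparameter, runs seeded three-way
#' repetitions and scores the mean misclassification error on the validation
#' part (the test part is never touched). Returns the spec with the
#' error-minimizing value; ties go to the smaller value. The repetition
#' seeds are shared across grid values, so every candidate sees the same
#' splits.
#'
#' @param base_spec a [classifier_spec()].
#' @param param name of the hyperparameter to tune (e.g. \code{"hidden"} for
#'   the MLP, default grid 2..13).
#' @param grid candidate values, ordered or not.
#' @param data an \code{"acs_dataset"}.
#' @param scheme a three-way [split_scheme()].
#' @param seed master integer seed.
#' @param normalization as in [repeated_evaluation()].
#' @return The winning \code{"classifier_spec"}, with attributes
#'   \code{"grid"} and \code{"validation_error"} recording the search.
#' @export
model_select <- function(base_spec, param, grid, data, scheme, seed,
                         normalization = c("split", "global", "none")) {
  normalization <- match.arg(normalization)
  if (!length(grid)) stop("model selection error: empty grid")
  if (scheme$mode != "three_way")
    stop("model selection error: a three-way scheme is required")
  grid <- sort(grid)
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * scheme$reps),
                  ncol = 2L)
  if (normalization == "global")
    data <- apply_normalizer(data, fit_normalizer(data))
  verr <- numeric(length(grid))
  for (g in seq_along(grid)) {
    spec <- do.call(classifier_spec,
                    c(list(base_spec$kind),
                      utils::modifyList(base_spec$control,
                                        stats::setNames(list(grid[[g]]), param)),
                      list(seed = base_spec$seed)))
    errs <- numeric(scheme$reps)
    for (r in seq_len(scheme$reps)) {
      parts <- make_split(data, scheme, seeds[r, 1L])
      d <- data
      if (normalization == "split") {
        stats <- fit_normalizer(subset_acs(d, rows = parts$train))
        d <- apply_normalizer(d, stats)
      }
      train <- subset_acs(d, rows = parts$train)
      val <- subset_acs(d, rows = parts$validation)
      rspec <- spec
      rspec$seed <- seeds[r, 2L]
      model <- acs_fit(rspec, train, val)
      errs[r] <- mean(predict(model, val) != val$labels)
    }
    verr[g] <- mean(errs)
  }
  best <- which.min(verr)   # ties: which.min takes the first = smaller value
  out <- do.call(classifier_spec,
                 c(list(base_spec$kind),
                   utils::modifyList(base_spec$control,
                                     stats::setNames(list(grid[[best]]), param)),
                   list(seed = base_spec$seed)))
  attr(out, "grid") <- grid
  attr(out, "validation_error") <- verr
  out
}
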