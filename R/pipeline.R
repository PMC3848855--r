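#' Default classifier roster: evaluation protocol per learner
#'
#' The study protocol pairs each classifier with a splitting mode and a
#' repetition count: learners that tune or stop on a validation part use
#' three-way splits (ANFIS 50 reps, MLP 100, RBF 1000, bagged ID3 1000); the
#' rest use two-way splits with 1000 reps (ID3, GLM, k-NN, Naive Bayes).
#' The MLP entry also carries its hidden-node tuning grid (2..13).
#'
#' @param reps_scale multiplier applied to every repetition count (smoke
#'   profiles use values well below 1); counts are rounded up, minimum 1.
#' @return A list of roster entries \code{list(spec, mode, reps, tune)}.
#' @export
default_roster <- function(reps_scale = 1) {
  scale <- function(r) max(1L, as.integer(ceiling(r * reps_scale)))
  list(
    anfis = list(spec = classifier_spec("anfis"), mode = "three_way",
                 reps = scale(50L), tune = NULL),
    mlp = list(spec = classifier_spec("mlp"), mode = "three_way",
               reps = scale(100L),
               tune = list(param = "hidden", grid = mlp_hidden_grid(),
                           reps = scale(10L))),
    rbf = list(spec = classifier_spec("rbf"), mode = "three_way",
               reps = scale(1000L), tune = NULL),
    bagging_id3 = list(spec = classifier_spec("bagging_id3"),
                       mode = "three_way", reps = scale(1000L), tune = NULL),
    id3 = list(spec = classifier_spec("id3"), mode = "two_way",
               reps = scale(1000L), tune = NULL),
    glm = list(spec = classifier_spec("glm"), mode = "two_way",
               reps = scale(1000L), tune = NULL),
    knn = list(spec = classifier_spec("knn"), mode = "two_way",
               reps = scale(1000L), tune = NULL),
    naive_bayes = list(spec = classifier_spec("naive_bayes"),
                       mode = "two_way", reps = scale(1000L), tune = NULL))
}

#' Configuration of a full pipeline run
#'
#' @param data an \code{"acs_dataset"}, or a [generator_config()] from which
#'   one is drawn with the master seed.
#' @param roster classifier roster as from [default_roster()].
#' @param selection list of backward-elimination settings (\code{k_grid},
#'   \code{reps}, \code{split_fraction}), or \code{NULL} to skip selection
#'   and use \code{features}.
#' @param features fixed feature subset (labels) used when selection is
#'   skipped; \code{NULL} means all features.
#' @param normalization normalization scope passed through to evaluation.
#' @param priors CPM priors (\code{NULL}: empirical priors of the dataset).
#' @param cpm_mode \code{"per_run"} or \code{"pooled"} (see
#'   [summary.acs_eval()]).
#' @param seed master integer seed; every stage derives its seeds from it.
#' @return A \code{"run_config"}.
#' @export
run_config <- function(data, roster = default_roster(),
                       selection = list(k_grid = seq(3L, 13L, 2L),
                                        reps = 100L, split_fraction = 0.7),
                       features = NULL,
                       normalization = c("split", "global", "none"),
                       priors = NULL, cpm_mode = c("per_run", "pooled"),
                       seed = 1L) {
  stopifnot(inherits(data, "acs_dataset") || inherits(data, "generator_config"))
  kinds <- vapply(roster, function(e) e$spec$kind, character(1))
  if (anyDuplicated(names(roster)))
    stop("pipeline error: duplicate roster entries")
  structure(list(data = data, roster = roster, selection = selection,
                 features = features,
                 normalization = match.arg(normalization), priors = priors,
                 cpm_mode = match.arg(cpm_mode), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full study pipeline
#'
#' Obtains the dataset (generating it when the config holds a generator),
#' runs the k-NN-wrapped backward elimination and picks the best (subset, k),
#' restricts the data to the selected features, then evaluates every roster
#' classifier under its splitting protocol (tuning on the validation part
#' where the entry requests it) and aggregates accuracy, APM and CPM. Fully
#' deterministic given the master seed: the generator, selection and each
#' roster entry receive fixed offsets of it.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return An \code{"acs_report"}.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  data <- if (inherits(config$data, "generator_config")) {
    say("generating dataset (seed %d)", seed)
    generate_acs(config$data, seed)$dataset
  } else config$data
  if (!is.null(config$selection)) {
    sel_args <- config$selection
    say("feature selection: k in {%s}, %d reps",
        paste(sel_args$k_grid, collapse = ","), sel_args$reps)
    trace <- backward_eliminate(data, k_grid = sel_args$k_grid,
                                reps = sel_args$reps,
                                split_fraction = sel_args$split_fraction,
                                seed = seed + 1L)
    sel <- best_subset(trace)
    features <- sel$subset
  } else {
    trace <- NULL
    sel <- NULL
    features <- if (is.null(config$features))
      schema_labels(data$schema) else as.integer(config$features)
  }
  reduced <- subset_acs(data, features = features)
  dataset_priors <- empirical_priors(tabulate(data$labels,
                                              data$schema$n_classes))
  priors <- if (is.null(config$priors)) dataset_priors else config$priors
  results <- list()
  offset <- 100L
  for (nm in names(config$roster)) {
    entry <- config$roster[[nm]]
    spec <- entry$spec
    # a k selected by the wrapper search overrides the k-NN default
    if (spec$kind == "knn" && !is.null(sel))
      spec <- classifier_spec("knn", k = sel$k, seed = spec$seed)
    scheme <- split_scheme(entry$mode, reps = entry$reps)
    if (!is.null(entry$tune)) {
      say("%s: tuning '%s' over {%s}", nm, entry$tune$param,
          paste(entry$tune$grid, collapse = ","))
      tune_scheme <- split_scheme("three_way", reps = entry$tune$reps)
      spec <- model_select(spec, entry$tune$param, entry$tune$grid, reduced,
                           tune_scheme, seed + offset,
                           normalization = config$normalization)
    }
    say("%s: %d x %s evaluation", nm, entry$reps, entry$mode)
    ev <- suppressWarnings(
      repeated_evaluation(spec, reduced, scheme, seed + offset + 1L,
                          normalization = config$normalization))
    results[[nm]] <- summary(ev, priors = priors, cpm_mode = config$cpm_mode)
    results[[nm]]$spec <- spec
    offset <- offset + 100L
  }
  structure(list(selection = sel, trace = trace, features = features,
                 results = results, priors = priors, seed = seed,
                 n = nrow(data$values), timestamp = format(Sys.time())),
            class = "acs_report")
}

#' @export
print.acs_report <- function(x, ...) {
  cat(sprintf("ACS pipeline report (n = %d, seed = %d)\n", x$n, x$seed))
  if (!is.null(x$selection)) {
    cat(sprintf("selected features (k = %d): {%s}\n", x$selection$k,
                paste(x$selection$subset, collapse = ", ")))
  } else {
    cat(sprintf("features: {%s}\n", paste(x$features, collapse = ", ")))
  }
  cat("overall accuracy (%):\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-12s %6.2f +/- %.2f  (%d reps)\n", nm,
                100 * r$accuracy$mean, 100 * r$accuracy$sd, r$reps))
  }
  invisible(x)
}

#' APM / CPM diagonals of a report, as bar-plot-ready tables
#'
#' @param report an \code{"acs_report"}.
#' @return A list of two matrices (classifiers x classes): the mean APM
#'   diagonal (per-class accuracy probability) and the mean CPM diagonal
#'   (per-class correctness probability).
#' @export
report_diagonals <- function(report) {
  cls <- names(report$results)
  apm <- t(vapply(report$results, function(r) diag(r$apm$mean),
                  numeric(length(report$priors))))
  cpm <- t(vapply(report$results, function(r) diag(r$cpm$mean),
                  numeric(length(report$priors))))
  rownames(apm) <- rownames(cpm) <- cls
  list(apm_diagonal = apm, cpm_diagonal = cpm)
}
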