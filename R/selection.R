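#' Wrapper evaluation of a feature subset with k-NN
#'
#' Scores a feature subset by the mean test accuracy of a k-NN classifier
#' restricted to it, over \code{reps} stratified two-way splits. The split
#' seeds derive only from \code{seed} (not from the subset), so every subset
#' evaluated under the same seed sees the same splits — the common-random-
#' numbers design that makes subset comparisons and the backward-elimination
#' search deterministic and exactly replayable. Ratio features are min-max
#' normalized with statistics fitted on each repetition's training part.
#'
#' @param data an \code{"acs_dataset"}.
#' @param subset non-empty vector of feature labels.
#' @param k neighbour count.
#' @param reps number of repetitions (default 100).
#' @param split_fraction training fraction of each two-way split (default 0.7).
#' @param seed integer seed.
#' @return Mean test accuracy over the repetitions.
#' @export
evaluate_subset <- function(data, subset, k, reps = 100L,
                            split_fraction = 0.7, seed = 1L) {
  if (!length(subset)) stop("selection error: empty feature subset")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("selection error: split_fraction must be in (0, 1)")
  ctx <- selection_context(data, reps, split_fraction, seed)
  cols <- match(as.integer(subset), schema_labels(data$schema))
  if (anyNA(cols)) stop("selection error: subset label not in schema")
  if (k > min(vapply(ctx, function(r) length(r$train), integer(1))))
    stop("selection error: k exceeds the training-split size")
  C <- data$schema$n_classes
  acc <- vapply(ctx, function(r) {
    pred <- knn_predict_cpp(r$X[r$train, cols, drop = FALSE],
                            data$labels[r$train],
                            r$X[r$test, cols, drop = FALSE], k, C)
    mean(pred == data$labels[r$test])
  }, numeric(1))
  mean(acc)
}

# Precompute, per repetition, the stratified split and the full feature
# matrix normalized with training-part statistics. Seeds are drawn once from
# the master seed so the context is identical for every subset.
selection_context <- function(data, reps, split_fraction, seed) {
  scheme <- split_scheme("two_way", c(split_fraction, 1 - split_fraction),
                         reps = reps)
  set.seed(as.integer(seed))
  split_seeds <- sample.int(.Machine$integer.max, reps)
  lapply(seq_len(reps), function(r) {
    parts <- make_split(data, scheme, split_seeds[r])
    stats <- fit_normalizer(subset_acs(data, rows = parts$train))
    Xn <- apply_normalizer(data, stats)$values
    list(train = parts$train, test = parts$test, X = Xn)
  })
}

#' Sequential backward elimination wrapped around k-NN
#'
#' For each k in the grid, starts from the full feature set and repeatedly
#' removes the feature whose removal gives the highest wrapper accuracy
#' (evaluated over the shared seeded splits of [evaluate_subset()]), until a
#' single feature remains. The full search is recorded: for every k, the
#' full-set accuracy plus, per elimination round, every leave-one-out
#' candidate subset, its mean accuracy, and the argmax choice.
#'
#' @param data an \code{"acs_dataset"}.
#' @param k_grid neighbour counts to search (default odd values 3 to 13).
#' @param reps repetitions per subset evaluation (default 100).
#' @param split_fraction training fraction (default 0.7).
#' @param seed integer seed; the whole search is deterministic given it.
#' @return A \code{"selection_trace"}.
#' @seealso [best_subset()]
#' @export
backward_eliminate <- function(data, k_grid = seq(3L, 13L, by = 2L),
                               reps = 100L, split_fraction = 0.7, seed = 1L) {
  if (!length(k_grid)) stop("selection error: empty k grid")
  labels <- schema_labels(data$schema)
  ctx <- selection_context(data, reps, split_fraction, seed)
  C <- data$schema$n_classes
  min_train <- min(vapply(ctx, function(r) length(r$train), integer(1)))
  if (max(k_grid) > min_train)
    stop("selection error: k exceeds the training-split size")
  eval_full <- function(cols, k) {
    mean(vapply(ctx, function(r) {
      pred <- knn_predict_cpp(r$X[r$train, cols, drop = FALSE],
                              data$labels[r$train],
                              r$X[r$test, cols, drop = FALSE], k, C)
      mean(pred == data$labels[r$test])
    }, numeric(1)))
  }
  eval_candidates <- function(cols, k) {
    # mean accuracy of each leave-one-feature-out candidate, reps averaged
    acc <- numeric(length(cols))
    for (r in ctx) {
      acc <- acc + knn_candidate_acc_cpp(r$X[r$train, cols, drop = FALSE],
                                         data$labels[r$train],
                                         r$X[r$test, cols, drop = FALSE],
                                         data$labels[r$test], k, C)
    }
    acc / length(ctx)
  }
  per_k <- lapply(as.integer(k_grid), function(k) {
    cols <- seq_along(labels)
    rounds <- list()
    full_acc <- eval_full(cols, k)
    round_no <- 0L
    while (length(cols) > 1L) {
      round_no <- round_no + 1L
      acc <- eval_candidates(cols, k)
      i_star <- which.max(acc)
      rounds[[round_no]] <- list(
        round = round_no, subset = labels[cols],
        candidates = lapply(seq_along(cols), function(i) labels[cols[-i]]),
        accuracies = acc, chosen = i_star)
      cols <- cols[-i_star]
    }
    list(k = k, full_subset = labels, full_accuracy = full_acc,
         rounds = rounds, final = labels[cols])
  })
  structure(list(per_k = per_k, k_grid = as.integer(k_grid),
                 reps = as.integer(reps), split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("backward-elimination trace: k in {%s}, %d reps, seed %d\n",
              paste(x$k_grid, collapse = ", "), x$reps, x$seed))
  for (pk in x$per_k) {
    best <- best_subset_one_k(pk)
    cat(sprintf("  k=%2d: best |S|=%d, accuracy %.4f\n", pk$k,
                length(best$subset), best$accuracy))
  }
  invisible(x)
}

# flat view of every (subset, accuracy) entry recorded for one k
entries_one_k <- function(pk) {
  ent <- list(list(subset = pk$full_subset, accuracy = pk$full_accuracy,
                   k = pk$k, round = 0L))
  for (rd in pk$rounds)
    for (i in seq_along(rd$candidates))
      ent[[length(ent) + 1L]] <- list(subset = rd$candidates[[i]],
                                      accuracy = rd$accuracies[i],
                                      k = pk$k, round = rd$round)
  ent
}

best_subset_one_k <- function(pk) {
  ent <- entries_one_k(pk)
  pick_best_entry(ent)
}

# global tie rules: higher accuracy, then smaller subset, then smaller k,
# then earlier round
pick_best_entry <- function(entries) {
  best <- entries[[1L]]
  for (e in entries[-1L]) {
    if (e$accuracy > best$accuracy ||
        (e$accuracy == best$accuracy &&
         (length(e$subset) < length(best$subset) ||
          (length(e$subset) == length(best$subset) &&
           (e$k < best$k ||
            (e$k == best$k && e$round < best$round))))))
      best <- e
  }
  best
}

#' Best subset of a backward-elimination trace
#'
#' The global argmax of mean wrapper accuracy over every (k, candidate
#' subset) pair recorded in the trace, including each k's full feature set.
#' Ties are broken toward the smaller subset, then the smaller k, then the
#' earlier elimination round.
#'
#' @param trace a \code{"selection_trace"} from [backward_eliminate()].
#' @return A \code{"selection_result"}: \code{subset} (feature labels),
#'   \code{k}, \code{accuracy}, and the per-k bests for reporting.
#' @export
best_subset <- function(trace) {
  stopifnot(inherits(trace, "selection_trace"))
  all_entries <- unlist(lapply(trace$per_k, entries_one_k), recursive = FALSE)
  best <- pick_best_entry(all_entries)
  per_k <- lapply(trace$per_k, best_subset_one_k)
  structure(list(subset = sort(best$subset), k = best$k,
                 accuracy = best$accuracy, round = best$round,
                 per_k = per_k),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selected subset (k=%d, accuracy %.4f): {%s}\n", x$k,
              x$accuracy, paste(x$subset, collapse = ", ")))
  invisible(x)
}

#' Jaccard similarity of two feature sets
#' @param a,b vectors of feature labels.
#' @return |a intersect b| / |a union b|.
#' @export
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
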