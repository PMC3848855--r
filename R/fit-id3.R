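# ID3 decision tree over mixed feature scales. Splits maximize information
# gain with entropy measured in bits; categorical features split multiway
# over their observed codes, ratio features by the best binary threshold at
# candidate midpoints between sorted distinct values. Growth stops at pure
# nodes, nodes below 'min_split', 'max_depth', or when no split has positive
# gain. Leaves predict the local majority class (ties to the lower class
# index); a categorical code unseen at a node during training falls through
# to that node's majority class.

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# best (gain, threshold) of a numeric feature via one sorted sweep
best_threshold <- function(x, y, C, H) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  cum <- apply(one_hot(ys, C), 2, cumsum)   # n x C cumulative counts
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  cuts <- which(xs[-n] < xs[-1])            # positions between distinct values
  if (!length(cuts)) return(NULL)
  best <- list(gain = -Inf, threshold = NA_real_)
  total <- cum[n, ]
  for (i in cuts) {
    left <- cum[i, ]; right <- total - left
    cond <- (i / n) * entropy_bits(left) + ((n - i) / n) * entropy_bits(right)
    g <- H - cond
    if (g > best$gain + 1e-12) {
      best$gain <- g
      best$threshold <- (xs[i] + xs[i + 1]) / 2
    }
  }
  best
}

grow_id3 <- function(X, y, scales, C, min_split, max_depth, depth = 0L) {
  counts <- tabulate(y, C)
  maj <- which.max(counts)
  H <- entropy_bits(counts)
  n <- length(y)
  if (H == 0 || n < min_split || depth >= max_depth)
    return(list(leaf = TRUE, class = maj))
  best <- list(gain = 0, feature = NA_integer_)
  for (j in seq_len(ncol(X))) {
    if (scales[j] == "ratio") {
      bt <- best_threshold(X[, j], y, C, H)
      if (!is.null(bt) && bt$gain > best$gain + 1e-12)
        best <- list(gain = bt$gain, feature = j, type = "num",
                     threshold = bt$threshold)
    } else {
      vals <- unique(X[, j])
      if (length(vals) < 2L) next
      cond <- 0
      for (v in vals) {
        sel <- X[, j] == v
        cond <- cond + (sum(sel) / n) * entropy_bits(tabulate(y[sel], C))
      }
      g <- H - cond
      if (g > best$gain + 1e-12)
        best <- list(gain = g, feature = j, type = "cat", values = sort(vals))
    }
  }
  if (is.na(best$feature)) return(list(leaf = TRUE, class = maj))
  j <- best$feature
  if (best$type == "num") {
    sel <- X[, j] <= best$threshold
    list(leaf = FALSE, feature = j, type = "num", threshold = best$threshold,
         maj = maj,
         left = grow_id3(X[sel, , drop = FALSE], y[sel], scales, C,
                         min_split, max_depth, depth + 1L),
         right = grow_id3(X[!sel, , drop = FALSE], y[!sel], scales, C,
                          min_split, max_depth, depth + 1L))
  } else {
    children <- list()
    for (v in best$values) {
      sel <- X[, j] == v
      children[[as.character(v)]] <-
        grow_id3(X[sel, , drop = FALSE], y[sel], scales, C,
                 min_split, max_depth, depth + 1L)
    }
    list(leaf = FALSE, feature = j, type = "cat", maj = maj,
         children = children)
  }
}

predict_tree <- function(node, x) {
  while (!node$leaf) {
    if (node$type == "num") {
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    } else {
      child <- node$children[[as.character(x[node$feature])]]
      if (is.null(child)) return(node$maj)  # unseen code at this node
      node <- child
    }
  }
  node$class
}

fit_id3_impl <- function(control, train, validation, seed) {
  list(tree = grow_id3(train$values, train$labels,
                       schema_scales(train$schema), train$schema$n_classes,
                       control$min_split, control$max_depth))
}

#' @export
model_classify.acs_id3 <- function(object, X) {
  vapply(seq_len(nrow(X)), function(i) predict_tree(object$tree, X[i, ]),
         numeric(1))
}

#' @export
print.acs_id3 <- function(x, ...) {
  depth <- function(nd) if (nd$leaf) 0L else {
    kids <- if (nd$type == "num") list(nd$left, nd$right) else nd$children
    1L + max(vapply(kids, depth, integer(1)))
  }
  cat(sprintf("ID3 decision tree, depth %d\n", depth(x$tree)))
  invisible(x)
}

# Bagged ID3: B trees grown on seeded bootstrap resamples (size n, with
# replacement), combined by plurality vote with ties to the lower class
# index. resample = "identity" is a test hook that disables resampling so
# B = 1 reduces exactly to plain ID3.
fit_bagging_impl <- function(control, train, validation, seed) {
  B <- as.integer(control$B)
  if (B < 1L) stop("bagging error: B must be a positive integer")
  resample <- match.arg(control$resample, c("bootstrap", "identity"))
  n <- nrow(train$values)
  scales <- schema_scales(train$schema)
  C <- train$schema$n_classes
  set.seed(seed)
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- if (resample == "bootstrap") sample.int(n, n, replace = TRUE)
            else seq_len(n)
    trees[[b]] <- grow_id3(train$values[rows, , drop = FALSE],
                           train$labels[rows], scales, C,
                           control$min_split, control$max_depth)
  }
  list(trees = trees, B = B)
}

#' @export
model_classify.acs_bagging_id3 <- function(object, X) {
  C <- object$n_classes
  votes <- matrix(0L, nrow(X), C)
  for (tr in object$trees) {
    pred <- vapply(seq_len(nrow(X)), function(i) predict_tree(tr, X[i, ]),
                   numeric(1))
    votes[cbind(seq_len(nrow(X)), pred)] <-
      votes[cbind(seq_len(nrow(X)), pred)] + 1L
  }
  argmax_rows(votes)
}

#' @export
print.acs_bagging_id3 <- function(x, ...) {
  cat(sprintf("bagged ID3 ensemble: %d trees\n", x$B))
  invisible(x)
}
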