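test_that("GLM links follow the distribution table and the normal fit is closed-form", {
  d <- dataset_1d(c(rep(-1, 5), rep(1, 5)), rep(1:2, each = 5))
  m <- acs_fit(classifier_spec("glm"), d)
  expect_equal(m$link, "identity")
  # least-squares solution: class scores (1 - x)/2 and (1 + x)/2
  expect_equal(unname(m$coefficients[, 1]), c(0.5, -0.5), tolerance = 1e-10)
  expect_equal(unname(m$coefficients[, 2]), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(predict(m, matrix(0.6)), 2L)
  expect_equal(predict(m, matrix(-0.6)), 1L)
  mp <- acs_fit(classifier_spec("glm", distribution = "poisson"), d)
  expect_equal(mp$link, "log")
  mi <- acs_fit(classifier_spec("glm", distribution = "inverse_gaussian"), d)
  expect_equal(mi$link, "1/mu^2")
  mg <- acs_fit(classifier_spec("glm", distribution = "gamma"), d)
  expect_equal(mg$link, "inverse")
})

test_that("GLM normal fit matches the closed-form least-squares oracle on random designs", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(90), 30, 3)
    y <- sample(1:3, 30, replace = TRUE)
    d <- acs_dataset(X, y, ratio_schema(3, C = 3))
    m <- acs_fit(classifier_spec("glm"), d)
    Xd <- cbind(1, X)
    B_ref <- solve(crossprod(Xd), crossprod(Xd, one_hot_test(y, 3)))
    expect_lt(max(abs(unname(m$coefficients) - B_ref)), 1e-8)
  }
})

test_that("GLM degenerate cases: one-class fit and singular designs", {
  d <- dataset_1d(c(0.1, 0.5, 0.9), c(2, 2, 2), C = 3)
  m <- acs_fit(classifier_spec("glm"), d)
  expect_equal(predict(m, matrix(c(-5, 0, 5))), c(2L, 2L, 2L))
  # a feature collinear with another is named in the error
  X <- cbind(rnorm(10), 0)
  X[, 2] <- 2 * X[, 1]
  dd <- acs_dataset(X, rep(1:2, 5), ratio_schema(2))
  expect_error(acs_fit(classifier_spec("glm"), dd), "collinear.*x2")
})

test_that("label-encoded GLM rounds the regressed output to the nearest class", {
  d <- dataset_1d(c(rep(0, 4), rep(1, 4), rep(2, 4)), rep(1:3, each = 4), C = 3)
  m <- acs_fit(classifier_spec("glm", encoding = "label"), d)
  expect_equal(predict(m, matrix(c(0, 1, 2))), c(1L, 2L, 3L))
})

test_that("k-NN reproduces hand-worked neighbourhoods and defaults to k = 7", {
  expect_equal(classifier_spec("knn")$control$k, 7L)
  expect_error(classifier_spec("knn", k = 4), "odd")
  d <- dataset_1d(c(0.0, 0.1, 1.0, 1.1), c(1, 1, 2, 2))
  m3 <- acs_fit(classifier_spec("knn", k = 3), d)
  # neighbours of 0.05 are 0.0, 0.1, 1.0 -> majority class 1
  expect_equal(predict(m3, matrix(0.05)), 1L)
  m1 <- acs_fit(classifier_spec("knn", k = 1), d)
  expect_equal(predict(m1, matrix(1.1)), 2L)  # zero-distance neighbour
  expect_error(acs_fit(classifier_spec("knn", k = 5), d), "exceeds")
})

test_that("k-NN agrees with the full-distance-matrix oracle on random instances", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    p <- sample(2:5, 1)
    C <- sample(2:4, 1)
    Xtr <- matrix(rnorm(n * p), n, p)
    ytr <- sample(seq_len(C), n, replace = TRUE)
    Xte <- matrix(rnorm(40 * p), 40, p)
    d <- acs_dataset(Xtr, ytr, ratio_schema(p, C))
    for (k in c(1L, 7L)) {
      m <- acs_fit(classifier_spec("knn", k = k), d)
      expect_equal(predict(m, Xte), as.integer(knn_oracle(Xtr, ytr, Xte, k, C)))
    }
  }
})

test_that("1-NN attains perfect training accuracy on distinct, consistently labeled data", {
  set.seed(8)
  X <- matrix(rnorm(80), 40, 2)
  y <- sample(1:3, 40, replace = TRUE)
  d <- acs_dataset(X, y, ratio_schema(2, C = 3))
  m <- acs_fit(classifier_spec("knn", k = 1), d)
  expect_equal(predict(m, d), y)
})

test_that("Naive Bayes posterior matches hand Bayes computation", {
  # one binary feature: P(c1 | f=1) = 0.5 / (0.5 + 0.5/3) = 0.75
  sch <- nominal_schema(1, codes = c(1, 2))
  d <- acs_dataset(matrix(c(1, 1, 1, 2, 2, 1)), c(1, 1, 1, 2, 2, 2), sch)
  m <- acs_fit(classifier_spec("naive_bayes", alpha = 0), d)
  expect_equal(m$tables[[1]]$probs[, "1"], c(1, 1 / 3))
  expect_equal(predict(m, matrix(1)), 1L)
  expect_equal(predict(m, matrix(2)), 2L)
})

test_that("Naive Bayes floors zero within-class variance and stays finite", {
  d <- dataset_1d(c(0, 0, 1, 1), c(1, 1, 2, 2))
  m <- acs_fit(classifier_spec("naive_bayes"), d)
  p <- predict(m, matrix(c(0.1, 0.9)))
  expect_equal(p, c(1L, 2L))
})

test_that("Naive Bayes falls back to the majority class when conditionals are identical", {
  sch <- nominal_schema(1, codes = c(1, 2))
  # feature constant: conditionals equal, priors 2/3 vs 1/3
  d <- acs_dataset(matrix(rep(1, 6)), c(1, 1, 1, 1, 2, 2), sch)
  m <- acs_fit(classifier_spec("naive_bayes"), d)
  expect_equal(predict(m, matrix(c(1, 2))), c(1L, 1L))
})

test_that("Naive Bayes predictions agree with enumerated Bayes on categorical toys", {
  set.seed(12)
  for (rep in 1:5) {
    p <- sample(2:3, 1)
    K <- sample(2:3, 1)
    C <- sample(2:3, 1)
    n <- 40
    X <- matrix(sample(seq_len(K), n * p, replace = TRUE), n, p)
    y <- sample(seq_len(C), n, replace = TRUE)
    alpha <- sample(c(0.5, 1, 2), 1)
    d <- acs_dataset(X, y, nominal_schema(p, codes = seq_len(K), C = C))
    m <- acs_fit(classifier_spec("naive_bayes", alpha = alpha), d)
    grid <- as.matrix(expand.grid(rep(list(seq_len(K)), p)))
    # independent enumeration from raw counts
    ref <- apply(grid, 1, function(x) {
      post <- vapply(seq_len(C), function(c) {
        pr <- sum(y == c) / n
        cond <- vapply(seq_len(p), function(j)
          (sum(X[y == c, j] == x[j]) + alpha) / (sum(y == c) + alpha * K),
          numeric(1))
        pr * prod(cond)
      }, numeric(1))
      which.max(post)
    })
    expect_equal(predict(m, grid), as.integer(ref))
  }
})

test_that("ID3 finds the fully informative splits of hand-built examples", {
  sch <- nominal_schema(1, codes = c(1, 2))
  d <- acs_dataset(matrix(c(1, 1, 2, 2)), c(1, 1, 2, 2), sch)
  m <- acs_fit(classifier_spec("id3"), d)
  expect_false(m$tree$leaf)   # one split on the single feature, gain 1 bit
  expect_equal(m$tree$feature, 1L)
  expect_equal(predict(m, d), c(1L, 1L, 2L, 2L))
  # pure node: leaf, no split
  dp <- acs_dataset(matrix(c(1, 2, 1)), c(2, 2, 2), sch, check = FALSE)
  mp <- acs_fit(classifier_spec("id3"), dp)
  expect_true(mp$tree$leaf)
  expect_equal(mp$tree$class, 2L)
  # ratio feature: threshold at the midpoint 0.5
  dr <- dataset_1d(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 2, 2))
  mr <- acs_fit(classifier_spec("id3"), dr)
  expect_equal(mr$tree$threshold, 0.5)
  expect_equal(predict(mr, dr), c(1L, 1L, 2L, 2L))
})

test_that("ID3 root split agrees with an exhaustive information-gain scan", {
  set.seed(44)
  for (rep in 1:4) {
    n <- 50
    Xnum <- matrix(rnorm(n * 2), n, 2)
    Xcat <- sample(1:3, n, replace = TRUE)
    y <- sample(1:2, n, replace = TRUE, prob = c(0.4, 0.6))
    sch <- acs_schema(list(
      list(label = 1, name = "x1", scale = "ratio"),
      list(label = 2, name = "x2", scale = "ratio"),
      list(label = 3, name = "g", scale = "nominal", codes = 1:3)),
      n_classes = 2, class_names = c("a", "b"))
    d <- acs_dataset(cbind(Xnum, Xcat), y, sch)
    m <- acs_fit(classifier_spec("id3"), d)
    # exhaustive scan over all features and all midpoint thresholds
    ent <- function(yy) {
      p <- tabulate(yy, 2) / length(yy); p <- p[p > 0]; -sum(p * log2(p))
    }
    H <- ent(y)
    best_gain <- -Inf; best_feat <- NA
    for (j in 1:3) {
      x <- d$values[, j]
      if (j == 3) {
        cond <- sum(vapply(unique(x), function(v)
          mean(x == v) * ent(y[x == v]), numeric(1)))
        g <- H - cond
        if (g > best_gain) { best_gain <- g; best_feat <- j }
      } else {
        vs <- sort(unique(x))
        for (t in (vs[-1] + vs[-length(vs)]) / 2) {
          sel <- x <= t
          g <- H - mean(sel) * ent(y[sel]) - mean(!sel) * ent(y[!sel])
          if (g > best_gain) { best_gain <- g; best_feat <- j }
        }
      }
    }
    expect_equal(m$tree$feature, best_feat)
  }
})

test_that("bagged ID3 reduces to plain ID3 under identity resampling", {
  set.seed(2)
  gen <- generate_acs(default_acs_config(n = 120), 3)
  d <- subset_acs(gen$dataset, features = c(31L, 40L, 36L))
  m_id3 <- acs_fit(classifier_spec("id3"), d)
  m_bag <- acs_fit(classifier_spec("bagging_id3", B = 1L, resample = "identity"),
                   d)
  expect_equal(predict(m_bag, d), predict(m_id3, d))
})

test_that("bagging votes by plurality and is trivial on one-class data", {
  # hand-built ensemble of three leaf-trees voting 1, 1, 2
  stub <- structure(list(trees = list(list(leaf = TRUE, class = 1L),
                                      list(leaf = TRUE, class = 1L),
                                      list(leaf = TRUE, class = 2L)),
                         B = 3L, kind = "bagging_id3", n_classes = 2L, p = 1L,
                         feature_names = "x"),
                    class = c("acs_bagging_id3", "acs_model"))
  expect_equal(predict(stub, matrix(c(0, 9))), c(1L, 1L))
  d <- dataset_1d(c(0.2, 0.4, 0.6), c(2, 2, 2), C = 2)
  m <- acs_fit(classifier_spec("bagging_id3", B = 5L), d)
  expect_equal(predict(m, matrix(c(-1, 0.5, 2))), c(2L, 2L, 2L))
})

test_that("bagging does not hurt the unstable base learner on study-like data", {
  gen <- generate_acs(default_acs_config(n = 400), 13)
  d <- subset_acs(gen$dataset, features = c(4L, 10L, 27L, 30L, 31L, 36L, 40L))
  sc <- split_scheme("two_way", reps = 50)
  acc_id3 <- summary(repeated_evaluation(classifier_spec("id3"), d, sc,
                                         seed = 5))$accuracy$mean
  acc_bag <- summary(suppressWarnings(
    repeated_evaluation(classifier_spec("bagging_id3", B = 25L), d, sc,
                        seed = 5)))$accuracy$mean
  expect_gte(acc_bag, acc_id3 - 0.01)
})

test_that("the MLP learns a linearly separable problem to perfect training accuracy", {
  set.seed(6)
  x <- c(rnorm(10, -1, 0.2), rnorm(10, 1, 0.2))
  d <- dataset_1d(x, rep(1:2, each = 10))
  m <- acs_fit(classifier_spec("mlp", hidden = 2L, epochs = 3000L, lr = 1.0,
                               early_stopping = FALSE), d)
  expect_equal(predict(m, d), d$labels)
})

test_that("MLP protocol: early stopping needs validation, grid is 2..13, one-class is constant", {
  expect_equal(mlp_hidden_grid(), 2:13)
  d <- dataset_1d(c(0.1, 0.9), c(1, 2))
  expect_error(acs_fit(classifier_spec("mlp"), d), "validation")
  dc <- dataset_1d(c(0.1, 0.5, 0.9), c(1, 1, 1), C = 2)
  m <- acs_fit(classifier_spec("mlp", epochs = 200L, early_stopping = FALSE), dc)
  expect_equal(predict(m, matrix(c(-1, 0, 1))), c(1L, 1L, 1L))
})

test_that("RBF with centers at every training point interpolates exactly", {
  d <- dataset_1d(c(0.1, 0.35, 0.6, 0.95), c(1, 2, 1, 2))
  m <- acs_fit(classifier_spec("rbf", centers = matrix(c(0.1, 0.35, 0.6, 0.95)),
                               lambda = 0), d)
  expect_equal(predict(m, d), d$labels)
  expect_equal(classifier_spec("rbf")$control$m, 7L)
  expect_error(acs_fit(classifier_spec("rbf", m = 5L), d), "distinct")
  dc <- dataset_1d(c(0.1, 0.5, 0.9), c(2, 2, 2), C = 2)
  mc <- acs_fit(classifier_spec("rbf", m = 2L), dc)
  expect_equal(predict(mc, matrix(c(0, 1))), c(2L, 2L))
})

test_that("the neuro-fuzzy consequent least squares reproduces a linear target exactly", {
  # one input, y = 2x + 1 on x in {0, 0.5, 1} -> labels {1, 2, 3}
  x <- rep(c(0, 0.5, 1), 3)
  d <- dataset_1d(x, rep(c(1, 2, 3), 3), C = 3)
  m <- acs_fit(classifier_spec("anfis", epochs = 0L), d)
  out <- acsclass:::anfis_output(m, d$values)
  expect_equal(out, 2 * x + 1, tolerance = 1e-5)
  expect_equal(predict(m, d), d$labels)
})

test_that("the neuro-fuzzy rule grid is capped and constant targets are reproduced", {
  set.seed(3)
  X <- matrix(rnorm(200), 20, 10)
  d <- acs_dataset(X, rep(1:2, 10), ratio_schema(10))
  expect_error(acs_fit(classifier_spec("anfis"), d), "cap")
  dc <- dataset_1d(c(0.2, 0.4, 0.6, 0.8), rep(2, 4), C = 3)
  m <- acs_fit(classifier_spec("anfis", epochs = 2L), dc)
  expect_equal(predict(m, dc), rep(2L, 4))
})

test_that("the prediction contract holds: empty input, width checks, determinism", {
  d <- dataset_1d(c(0, 1), c(1, 2))
  m <- acs_fit(classifier_spec("knn", k = 1), d)
  expect_identical(predict(m, matrix(numeric(0), 0, 1)), integer(0))
  expect_error(predict(m, matrix(0, 1, 3)), "width")
  q <- matrix(0.4)
  expect_identical(predict(m, q), predict(m, q))
})

test_that("stochastic trainers are bit-for-bit reproducible under a fixed seed", {
  gen <- generate_acs(default_acs_config(n = 150), 4)
  d <- subset_acs(gen$dataset, features = c(31L, 36L, 40L))
  sc <- split_scheme("three_way", reps = 1)
  parts <- make_split(d, sc, 9)
  tr <- subset_acs(d, rows = parts$train)
  va <- subset_acs(d, rows = parts$validation)
  for (kind in c("mlp", "rbf", "bagging_id3", "anfis")) {
    ctl <- if (kind == "anfis") list(epochs = 2L) else list()
    s1 <- do.call(classifier_spec, c(list(kind), ctl, list(seed = 42L)))
    m1 <- acs_fit(s1, tr, va)
    m2 <- acs_fit(s1, tr, va)
    expect_identical(m1, m2)
    expect_identical(predict(m1, d), predict(m2, d))
  }
})
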