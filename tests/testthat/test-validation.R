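test_that("stratified apportionment reproduces the registry's 0.7/0.3 part counts", {
  cfg <- default_acs_config(n = c(224L, 128L, 417L, 40L))
  d <- generate_acs(cfg, 1)$dataset
  parts <- make_split(d, split_scheme("two_way"), seed = 3)
  expect_equal(tabulate(d$labels[parts$test], 4), c(67L, 39L, 125L, 12L))
  expect_equal(tabulate(d$labels[parts$train], 4), c(157L, 89L, 292L, 28L))
  expect_equal(length(parts$test), 243L)
})

test_that("scheme fractions are validated and parts are disjoint and exhaustive", {
  expect_error(split_scheme("two_way", c(0.5, 0.6)), "sum to 1")
  expect_error(split_scheme("two_way", c(0.7, 0.3), reps = 0), "reps")
  d <- generate_acs(default_acs_config(n = 101), 2)$dataset
  for (scheme in list(split_scheme("two_way"),
                      split_scheme("three_way"),
                      split_scheme("two_way", stratified = FALSE))) {
    for (seed in c(1, 17)) {
      parts <- make_split(d, scheme, seed)
      all_idx <- sort(unname(unlist(parts)))
      expect_equal(all_idx, seq_len(101L))
      expect_equal(sum(lengths(parts)), 101L)
    }
  }
  # same seed -> identical partition
  s <- split_scheme("three_way")
  expect_identical(make_split(d, s, 5), make_split(d, s, 5))
})

test_that("stratified splits preserve class proportions within one sample per part", {
  d <- generate_acs(default_acs_config(n = 400), 8)$dataset
  scheme <- split_scheme("three_way")
  parts <- make_split(d, scheme, 11)
  counts <- tabulate(d$labels, 4)
  for (j in seq_along(parts)) {
    got <- tabulate(d$labels[parts[[j]]], 4)
    expect_true(all(abs(got - counts * scheme$fractions[j]) <= 1))
  }
})

test_that("a class too small to stratify raises an error", {
  sch <- ratio_schema(1, C = 2)
  d <- acs_dataset(matrix(rnorm(10)), c(rep(1, 9), 2), sch)
  expect_error(make_split(d, split_scheme("three_way"), 1), "too small")
})

test_that("repeated evaluation builds one test confusion matrix per repetition", {
  d <- generate_acs(default_acs_config(n = 120), 5)$dataset
  d <- subset_acs(d, features = c(31L, 40L))
  ev <- repeated_evaluation(classifier_spec("naive_bayes"), d,
                            split_scheme("two_way", reps = 1), seed = 7)
  expect_length(ev$runs, 1L)
  expect_equal(sum(ev$runs[[1]]$cm), 36L)   # 0.3 of 120
  # same master seed -> identical run lists
  ev2 <- repeated_evaluation(classifier_spec("naive_bayes"), d,
                             split_scheme("two_way", reps = 3), seed = 9)
  ev3 <- repeated_evaluation(classifier_spec("naive_bayes"), d,
                             split_scheme("two_way", reps = 3), seed = 9)
  expect_identical(lapply(ev2$runs, `[[`, "cm"), lapply(ev3$runs, `[[`, "cm"))
})

test_that("kinds that expect a validation part warn under a two-way scheme", {
  d <- generate_acs(default_acs_config(n = 100), 6)$dataset
  d <- subset_acs(d, features = c(31L, 40L))
  expect_warning(
    repeated_evaluation(classifier_spec("bagging_id3", B = 3L), d,
                        split_scheme("two_way", reps = 1), seed = 1),
    "three-way")
  expect_error(
    repeated_evaluation(classifier_spec("bagging_id3", B = 3L), d,
                        split_scheme("two_way", reps = 1), seed = 1,
                        strict = TRUE),
    "three-way")
})

test_that("model selection returns the grid value minimizing validation error", {
  d <- generate_acs(default_acs_config(n = c(50L, 30L, 55L, 15L)), 3)$dataset
  d <- subset_acs(d, features = c(31L, 36L, 40L))
  spec <- model_select(classifier_spec("naive_bayes"), "alpha", 1,
                       d, split_scheme("three_way", reps = 2), seed = 4)
  expect_equal(spec$control$alpha, 1)
  expect_error(model_select(classifier_spec("naive_bayes"), "alpha", 1, d,
                            split_scheme("two_way", reps = 2), seed = 4),
               "three-way")
  expect_error(model_select(classifier_spec("naive_bayes"), "alpha",
                            numeric(0), d,
                            split_scheme("three_way", reps = 2), seed = 4),
               "empty")
})

test_that("hidden-node selection prefers capacity when the boundary demands it", {
  sch1 <- ratio_schema(1, C = 2)
  mkdat <- function(seed, n = 240) {
    set.seed(seed)
    x <- runif(n, -1, 1)
    acs_dataset(matrix(x), ifelse(abs(x) < 0.5, 2L, 1L), sch1)
  }
  wins <- 0L
  for (s in 1:10) {
    spec <- model_select(
      classifier_spec("mlp", epochs = 2000L, lr = 1.0, patience = 100L),
      "hidden", c(1L, 4L), mkdat(s),
      split_scheme("three_way", reps = 2), seed = s)
    if (spec$control$hidden == 4L) wins <- wins + 1L
  }
  # one hidden unit cannot represent the non-monotone interval boundary
  expect_gte(wins, 9L)
})
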