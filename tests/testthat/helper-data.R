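# small programmatic fixtures shared across test files

make_binary_data <- function(n = 40, p = 20, seed = 1, prop_b = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("g", seq_len(p))))
    n_b <- round(n * prop_b)
    y <- factor(sample(rep(c("a", "b"), c(n - n_b, n_b))),
                levels = c("a", "b"))
  })
  list(X = X, y = y)
}

# one strongly separating predictor among noise
make_signal_data <- function(n = 60, p = 40, seed = 1, effect = 3) {
  d <- make_binary_data(n, p, seed)
  withr::with_seed(seed + 1000,
    d$X[, 1] <- ifelse(d$y == "b", effect, -effect) + rnorm(n, sd = 0.5))
  d
}

make_regression_data <- function(n = 50, p = 15, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("g", seq_len(p))))
    y <- X[, 1] * 2 + rnorm(n)
  })
  list(X = X, y = y)
}

small_en <- function(alpha = c(0.5, 1), n_lambda = 20) {
  elastic_net_learner(alpha = alpha, n_lambda = n_lambda)
}

expect_partition <- function(folds, n) {
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_len(n))
  expect_equal(sum(lengths(folds)), n)  # disjoint given the cover above
}
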