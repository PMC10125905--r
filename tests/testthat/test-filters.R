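# independent column-wise oracles -----------------------------------------

oracle_welch_t <- function(X, y) {
  apply(X, 2, function(x) {
    unname(abs(t.test(x[y == levels(y)[1]], x[y == levels(y)[2]])$statistic))
  })
}

oracle_rank_sum_z <- function(X, y) {
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  apply(X, 2, function(x) {
    r <- rank(x)
    U <- sum(r[g1]) - n1 * (n1 + 1) / 2       # Mann-Whitney U of group 1
    tie <- table(x)
    v <- n1 * n2 / 12 * (n + 1 - sum(tie^3 - tie) / (n * (n - 1)))
    if (v <= 0) 0 else abs((U - n1 * n2 / 2) / sqrt(v))
  })
}

oracle_anova_f <- function(X, y) {
  apply(X, 2, function(x) {
    unname(summary(stats::aov(x ~ y))[[1]][["F value"]][1])
  })
}

test_that("Welch t filter matches a per-column t.test oracle", {
  d <- make_binary_data(200, 50, seed = 21)
  fr <- ttest_filter(d$X, d$y, n_keep = 50)
  want <- oracle_welch_t(d$X, d$y)
  got <- fr$kept$score[order(fr$kept$index)]
  expect_equal(got, unname(want[sort(fr$kept$index)]), tolerance = 1e-10)
  # ranking is by descending |t|, ties by ascending index
  expect_identical(fr$kept$index, order(-want, seq_along(want))[1:50])
})

test_that("degenerate predictors are excluded, never kept", {
  d <- make_binary_data(30, 10, seed = 2)
  d$X[, 4] <- 7  # constant across all samples
  fr <- ttest_filter(d$X, d$y, n_keep = 10)
  expect_true(4 %in% fr$dropped_degenerate)
  expect_false(4 %in% kept_indices(fr))
  expect_equal(nrow(fr$kept), 9)
})

test_that("t filter keeps exactly n_keep predictors on wide noise data", {
  d <- make_binary_data(40, 500, seed = 3)
  fr <- ttest_filter(d$X, d$y, n_keep = 100)
  expect_length(kept_indices(fr), 100)
  expect_false(anyDuplicated(kept_indices(fr)) > 0)
})

test_that("rank-sum filter matches the Mann-Whitney oracle and is transform-invariant", {
  d <- make_binary_data(100, 20, seed = 31)
  d$X[, 5] <- round(d$X[, 5])  # induce ties
  fr <- wilcoxon_filter(d$X, d$y, n_keep = 20)
  want <- oracle_rank_sum_z(d$X, d$y)
  expect_equal(fr$kept$score[order(fr$kept$index)],
               unname(want[sort(fr$kept$index)]), tolerance = 1e-10)
  # monotone transform leaves rank statistics unchanged
  fr3 <- wilcoxon_filter(d$X^3, d$y, n_keep = 20)
  expect_identical(kept_indices(fr3), kept_indices(fr))

  d$X[, 2] <- 1  # all tied: statistic 0, ranked last among eligible
  fr0 <- wilcoxon_filter(d$X, d$y, n_keep = 20)
  expect_true(2 %in% fr0$dropped_degenerate ||
              fr0$kept$index[nrow(fr0$kept)] == 2)
})

test_that("ANOVA filter matches aov and reduces to pooled t-test with 2 classes", {
  d3 <- make_binary_data(150, 30, seed = 41)
  y3 <- factor(sample(c("a", "b", "c"), 150, replace = TRUE))
  while (min(table(y3)) < 2) y3 <- factor(sample(c("a", "b", "c"), 150, TRUE))
  fr <- anova_filter(d3$X, y3, n_keep = 30)
  want <- oracle_anova_f(d3$X, y3)
  expect_equal(fr$kept$score[order(fr$kept$index)],
               unname(want[sort(fr$kept$index)]), tolerance = 1e-10)

  # two classes: F equals the squared pooled-variance t statistic
  d <- make_binary_data(60, 15, seed = 5)
  fr2 <- anova_filter(d$X, d$y, n_keep = 15)
  t_pooled <- apply(d$X, 2, function(x) {
    unname(t.test(x[d$y == "a"], x[d$y == "b"], var.equal = TRUE)$statistic)
  })
  expect_equal(fr2$kept$score[order(fr2$kept$index)],
               unname(t_pooled[sort(fr2$kept$index)]^2), tolerance = 1e-10)

  expect_error(anova_filter(d$X, factor(c("a", rep("b", 59))), 5),
               class = "nestfold_degenerate_outcome")
})

test_that("correlation filter matches the closed-form covariance formula", {
  d <- make_regression_data(100, 25, seed = 51)
  fr <- correlation_filter(d$X, d$y, n_keep = 25, kind = "pearson")
  want <- apply(d$X, 2, function(x) {
    abs(sum((x - mean(x)) * (d$y - mean(d$y))) /
          sqrt(sum((x - mean(x))^2) * sum((d$y - mean(d$y))^2)))
  })
  expect_equal(fr$kept$score[order(fr$kept$index)],
               unname(want[sort(fr$kept$index)]), tolerance = 1e-10)

  # predictor equal to y ranks first with |r| = 1
  X2 <- cbind(yy = d$y, d$X)
  fr2 <- correlation_filter(X2, d$y, n_keep = 5)
  expect_equal(fr2$kept$index[1], 1)
  expect_equal(fr2$kept$score[1], 1)

  # spearman is invariant under monotone transforms
  frs <- correlation_filter(d$X, d$y, n_keep = 25, kind = "spearman")
  frs3 <- correlation_filter(d$X^3, d$y, n_keep = 25, kind = "spearman")
  expect_identical(kept_indices(frs), kept_indices(frs3))

  expect_error(correlation_filter(d$X, rep(1, 100), 5),
               class = "nestfold_degenerate_outcome")
})

test_that("random forest filter is seeded-deterministic and finds strong signal", {
  d <- make_signal_data(50, 30, seed = 61)
  a <- rf_importance_filter(d$X, d$y, n_keep = 5, n_trees = 200, seed = 4)
  b <- rf_importance_filter(d$X, d$y, n_keep = 5, n_trees = 200, seed = 4)
  expect_identical(a$kept, b$kept)
  expect_length(kept_indices(a), 5)

  hits <- vapply(1:20, function(s) {
    d <- make_signal_data(50, 30, seed = 100 + s)
    kept_indices(rf_importance_filter(d$X, d$y, 5, n_trees = 200,
                                      seed = s))[1] == 1
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("ReliefF matches a straight-loop oracle with exhaustive neighbors", {
  d <- make_binary_data(25, 8, seed = 71)
  k <- 3
  fr <- relieff_filter(d$X, d$y, n_keep = 8, n_neighbors = k,
                       n_samples_used = 25, seed = 9)

  # independent naive re-implementation of the update rule
  lo <- apply(d$X, 2, min); hi <- apply(d$X, 2, max)
  span <- ifelse(hi - lo == 0, 1, hi - lo)
  Xs <- sweep(sweep(d$X, 2, lo), 2, span, "/")
  n <- nrow(Xs); p <- ncol(Xs)
  prior <- table(d$y) / n
  W <- numeric(p)
  order_used <- withr::with_seed(9, sample(n, n))
  for (i in order_used) {
    for (cl in levels(d$y)) {
      members <- setdiff(which(d$y == cl), i)
      dists <- vapply(members, function(j) sum(abs(Xs[i, ] - Xs[j, ])),
                      numeric(1))
      nn <- members[order(dists, members)][seq_len(min(k, length(members)))]
      for (f in seq_len(p)) {
        md <- mean(abs(Xs[nn, f] - Xs[i, f]))
        if (cl == as.character(d$y[i])) {
          W[f] <- W[f] - md / n
        } else {
          W[f] <- W[f] + as.numeric(prior[cl]) /
            (1 - as.numeric(prior[as.character(d$y[i])])) * md / n
        }
      }
    }
  }
  expect_equal(fr$kept$score[order(fr$kept$index)],
               W[sort(fr$kept$index)], tolerance = 1e-10)
})

test_that("ReliefF gives weight 0 to constants and top weight to a label copy", {
  d <- make_binary_data(30, 6, seed = 81)
  d$X[, 3] <- 5                                   # constant
  d$X[, 1] <- as.numeric(d$y == "b")              # equals the class label
  fr <- relieff_filter(d$X, d$y, n_keep = 6, n_neighbors = 5, seed = 2)
  expect_true(3 %in% fr$dropped_degenerate)
  expect_equal(fr$kept$index[1], 1)               # label copy attains max weight
})

test_that("kept sets are prefix-monotone in n_keep", {
  d <- make_binary_data(50, 20, seed = 91)
  full <- kept_indices(ttest_filter(d$X, d$y, n_keep = 20))
  for (m in c(1, 5, 12, 19)) {
    expect_identical(kept_indices(ttest_filter(d$X, d$y, n_keep = m)),
                     full[1:m])
  }
})

test_that("apply_filter subsets and orders columns as kept_indices", {
  X <- matrix(1:12, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  fr <- structure(list(method = "custom",
                       kept = tibble::tibble(rank = 1:2, index = c(3L, 1L),
                                             predictor = c("c", "a"),
                                             score = c(2, 1)),
                       dropped_degenerate = integer(), n_keep = 2L),
                  class = "filter_result")
  out <- apply_filter(X, fr)
  expect_identical(out, X[, c(3, 1)])
  bad <- fr; bad$kept$index <- c(4L, 1L)
  expect_error(apply_filter(X, bad), class = "nestfold_contract_violation")
})

test_that("custom filters plug into the engine contract", {
  d <- make_binary_data(30, 10, seed = 15)
  spec <- filter_spec("custom", n_keep = 3,
                      fn = function(X, y, n_keep, seed, ...) {
                        ttest_filter(X, y, n_keep)
                      })
  fr <- nestfold:::run_filter(d$X, d$y, spec, seed = 1)
  expect_s3_class(fr, "filter_result")
  expect_length(kept_indices(fr), 3)
})

test_that("n_keep larger than the eligible set keeps all and warns", {
  d <- make_binary_data(20, 5, seed = 16)
  expect_warning(fr <- ttest_filter(d$X, d$y, n_keep = 50),
                 "eligible")
  expect_length(kept_indices(fr), 5)
})
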