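test_that("a one-point grid returns exactly that pair", {
  d <- make_binary_data(40, 10, seed = 1)
  inner <- make_stratified_folds(d$y, 4, seed = 2)
  tuned <- tune_elastic_net(d$X, d$y, inner,
                            elastic_net_learner(alpha = 0.5, lambda = 0.1))
  expect_equal(tuned$params$alpha, 0.5)
  expect_equal(tuned$params$lambda, 0.1)
})

test_that("the tuner's choice is never beaten on an exhaustive grid re-evaluation", {
  d <- make_binary_data(60, 20, seed = 8)
  inner <- make_stratified_folds(d$y, 4, seed = 3)
  learner <- elastic_net_learner(alpha = c(0.25, 1), n_lambda = 20)
  tuned <- tune_elastic_net(d$X, d$y, inner, learner)

  # independent loop over every grid point and inner fold
  dev <- function(p, ypos) {
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -2 * mean(ifelse(ypos, log(p), log(1 - p)))
  }
  best <- Inf
  for (a in c(0.25, 1)) {
    lam <- tuned$lambda_paths[[as.character(a)]]
    for (li in seq_along(lam)) {
      scores <- vapply(inner, function(hold) {
        fit <- glmnet::glmnet(d$X[-hold, ], d$y[-hold], family = "binomial",
                              alpha = a, lambda = lam)
        p <- predict(fit, d$X[hold, ], s = lam[li], type = "response")
        dev(as.vector(p), d$y[hold] == "b")
      }, numeric(1))
      m <- mean(scores)
      if (m < best) best <- m
      if (a == tuned$params$alpha && lam[li] == tuned$params$lambda) {
        expect_equal(m, tuned$score, tolerance = 1e-12)
      }
    }
  }
  expect_lte(tuned$score, best + 1e-12)
})

test_that("the path maximum nulls all coefficients (intercept-only model)", {
  d <- make_binary_data(50, 15, seed = 12)
  inner <- make_stratified_folds(d$y, 3, seed = 1)
  learner <- elastic_net_learner(alpha = 1, n_lambda = 10)
  tuned <- tune_elastic_net(d$X, d$y, inner, learner)
  lam_max <- max(tuned$lambda_paths[["1"]])
  fit <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 1,
                        lambda = tuned$lambda_paths[["1"]])
  expect_true(all(abs(coef(fit, s = lam_max)[-1]) < 1e-10))

  # intercept-only predictions equal the training prevalence
  tuned_max <- tuned
  tuned_max$params <- list(alpha = 1, lambda = lam_max)
  model <- nestfold:::nf_fit(learner, d$X, d$y, tuned_max, seed = 1)
  p <- predict_scores(model, d$X)
  expect_equal(unname(p), rep(mean(d$y == "b"), 50), tolerance = 1e-6)
})

test_that("score ties break toward larger lambda then larger alpha", {
  tab <- tibble::tibble(alpha = c(0.5, 1, 1), lambda = c(2, 2, 5),
                        score = c(1, 1, 1))
  ties <- which(tab$score == min(tab$score))
  best <- ties[order(-tab$lambda[ties], -tab$alpha[ties])][1]
  expect_equal(best, 3L)  # largest lambda wins; then alpha would
})

test_that("random forest fits are reproducible under a fixed seed", {
  d <- make_signal_data(40, 12, seed = 3)
  learner <- rf_learner(n_trees = 100)
  tuned <- nestfold:::nf_fixed_params(learner)
  m1 <- nestfold:::nf_fit(learner, d$X, d$y, tuned, seed = 7)
  m2 <- nestfold:::nf_fit(learner, d$X, d$y, tuned, seed = 7)
  expect_identical(predict_scores(m1, d$X), predict_scores(m2, d$X))
})

test_that("prediction aligns columns by name and rejects mismatches", {
  d <- make_binary_data(40, 8, seed = 5)
  inner <- make_stratified_folds(d$y, 3, seed = 1)
  learner <- elastic_net_learner(alpha = 1, n_lambda = 15)
  tuned <- tune_elastic_net(d$X, d$y, inner, learner)
  model <- nestfold:::nf_fit(learner, d$X, d$y, tuned, seed = 1)

  p0 <- predict_scores(model, d$X)
  expect_true(all(p0 >= 0 & p0 <= 1))
  # permuted column order gives identical scores
  perm <- d$X[, sample(ncol(d$X))]
  expect_equal(predict_scores(model, perm), p0)
  # missing predictor names are an explicit error
  expect_error(predict_scores(model, d$X[, -2]),
               class = "nestfold_contract_violation")
  expect_error(predict_scores(model, d$X[, -2]), "g2")
})

test_that("standardized-coefficient importance is scale-invariant", {
  d <- make_signal_data(60, 10, seed = 9)
  learner <- elastic_net_learner(alpha = 1, lambda = 0.05)
  tuned <- nestfold:::nf_fixed_params(learner)
  m1 <- nestfold:::nf_fit(learner, d$X, d$y, tuned, seed = 1)
  X2 <- d$X; X2[, 1] <- X2[, 1] * 2
  m2 <- nestfold:::nf_fit(learner, X2, d$y, tuned, seed = 1)
  i1 <- variable_importance(m1)
  i2 <- variable_importance(m2)
  expect_true(all(i1$importance >= 0))
  expect_equal(i2$importance[i2$predictor == "g1"],
               i1$importance[i1$predictor == "g1"], tolerance = 1e-4)
})

test_that("custom learners satisfy the engine contract", {
  d <- make_binary_data(40, 6, seed = 2)
  lrn <- custom_learner(
    name = "prevalence",
    fit = function(X, y, params, seed) mean(y == levels(y)[2]),
    predict = function(model, X) rep(model, nrow(X)))
  ds <- new_dataset(d$X, d$y)
  res <- outercv_fit(ds, k_outer = 4, learner = lrn, seed = 1, final = FALSE)
  expect_equal(unique(res$pooled$score), mean(d$y == "b"), tolerance = 1e-9)
})
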