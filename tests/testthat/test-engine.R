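tiny_nestcv <- function(ds, seed = 1, filter = filter_spec("ttest", n_keep = 10),
                        balance = NULL, learner = small_en(), k = 3, l = 2,
                        cores = 1, final = FALSE) {
  plan <- make_fold_plan(ds$y, k, l, seed = seed)
  nestcv_fit(ds, plan, filter = filter, balance = balance, learner = learner,
             cores = cores, final = final)
}

test_that("every sample is scored exactly once in the pooled predictions", {
  d <- make_binary_data(36, 25, seed = 1)
  ds <- new_dataset(d$X, d$y)
  res <- tiny_nestcv(ds)
  expect_equal(nrow(res$pooled), 36)
  expect_identical(sort(unlist(lapply(res$fold_records, `[[`, "test_idx"))),
                   1:36)
  expect_false(anyNA(res$pooled$score))
})

test_that("per-fold artifacts derive from training rows only (leakage sentinel)", {
  d <- make_binary_data(36, 20, seed = 4)
  ds <- new_dataset(d$X, d$y)
  res <- tiny_nestcv(ds, seed = 2)
  # corrupt fold 1's held-out rows after planning; nothing upstream of
  # prediction may change for that fold
  test1 <- res$fold_records[[1]]$test_idx
  ds2 <- ds
  withr::with_seed(99,
    ds2$X[test1, ] <- matrix(rnorm(length(test1) * ncol(ds$X)),
                             length(test1)))
  res2 <- tiny_nestcv(ds2, seed = 2)
  expect_identical(res2$fold_records[[1]]$filter,
                   res$fold_records[[1]]$filter)
  expect_identical(res2$fold_records[[1]]$tuned$params,
                   res$fold_records[[1]]$tuned$params)
  expect_identical(res2$fold_records[[1]]$tuned$score_table,
                   res$fold_records[[1]]$tuned$score_table)
  expect_false(identical(res2$fold_records[[1]]$scores,
                         res$fold_records[[1]]$scores))
})

test_that("a perfectly separating predictor is recovered with high pooled AUC", {
  d <- make_signal_data(60, 100, seed = 6, effect = 3)
  ds <- new_dataset(d$X, d$y)
  res <- tiny_nestcv(ds, seed = 3, k = 5, l = 3)
  expect_gte(res$metrics$auc, 0.95)
  # the signal predictor is selected in every fold
  for (rec in res$fold_records) {
    expect_true(1 %in% kept_indices(rec$filter))
  }
})

test_that("nested CV with a one-point grid equals outer-only CV exactly", {
  d <- make_binary_data(40, 15, seed = 7)
  ds <- new_dataset(d$X, d$y)
  fixed <- elastic_net_learner(alpha = 0.5, lambda = 0.08)
  plan <- make_fold_plan(ds$y, 4, 2, seed = 5)
  nested <- nestcv_fit(ds, plan, filter = filter_spec("ttest", n_keep = 8),
                       learner = fixed, final = FALSE)
  outer <- outercv_fit(ds, k_outer = 4, filter = filter_spec("ttest", n_keep = 8),
                       learner = fixed, seed = 5, final = FALSE)
  expect_equal(outer$pooled$score, nested$pooled$score, tolerance = 1e-12)
  expect_equal(outer$metrics$auc, nested$metrics$auc, tolerance = 1e-12)
  for (i in 1:4) {
    expect_identical(outer$fold_records[[i]]$filter,
                     nested$fold_records[[i]]$filter)
    expect_equal(outer$fold_records[[i]]$tuned$params,
                 nested$fold_records[[i]]$tuned$params)
  }
})

test_that("outer-fold filters differ across folds on noise data", {
  d <- make_binary_data(40, 200, seed = 8)
  ds <- new_dataset(d$X, d$y)
  res <- outercv_fit(ds, k_outer = 4, filter = filter_spec("ttest", n_keep = 10),
                     learner = elastic_net_learner(alpha = 1, lambda = 0.05),
                     seed = 2, final = FALSE)
  kept <- lapply(res$fold_records, function(r) kept_indices(r$filter))
  expect_gt(length(unique(kept)), 1)
})

test_that("outercv rejects learners that require tuning", {
  d <- make_binary_data(30, 10, seed = 9)
  ds <- new_dataset(d$X, d$y)
  expect_error(outercv_fit(ds, 3, learner = elastic_net_learner()),
               class = "nestfold_contract_violation")
})

test_that("results are invariant to the outer-loop worker count", {
  skip_on_os("windows")
  d <- make_binary_data(36, 30, seed = 10)
  ds <- new_dataset(d$X, d$y)
  r1 <- tiny_nestcv(ds, seed = 4, cores = 1)
  r2 <- tiny_nestcv(ds, seed = 4, cores = 2)
  expect_equal(r1$pooled, r2$pooled, tolerance = 1e-15)
  expect_identical(lapply(r1$fold_records, function(r) r$tuned$params),
                   lapply(r2$fold_records, function(r) r$tuned$params))
})

test_that("balancing is applied to outer training folds and refused for regression", {
  d <- make_binary_data(40, 15, seed = 11, prop_b = 0.25)
  ds <- new_dataset(d$X, d$y)
  res <- tiny_nestcv(ds, balance = balance_spec("oversample"),
                     filter = filter_spec("ttest", n_keep = 8))
  for (rec in res$fold_records) {
    expect_equal(rec$balance_summary$n_after[1],
                 rec$balance_summary$n_after[2])
  }
  # test rows are never balanced: pooled predictions still cover n samples
  expect_equal(nrow(res$pooled), 40)

  r <- make_regression_data(40, 10, seed = 1)
  dsr <- new_dataset(r$X, r$y)
  plan <- make_fold_plan(dsr$y, 3, 2, seed = 1)
  expect_error(nestcv_fit(dsr, plan, balance = balance_spec("smote"),
                          learner = elastic_net_learner(alpha = 1, lambda = 0.1)),
               class = "nestfold_balance_regression")
})

test_that("the engine supports regression outcomes with correlation filtering", {
  r <- make_regression_data(60, 40, seed = 13)
  ds <- new_dataset(r$X, r$y)
  plan <- make_fold_plan(ds$y, 4, 3, seed = 2)
  res <- nestcv_fit(ds, plan, filter = filter_spec("pearson", n_keep = 10),
                    learner = small_en(), final = FALSE)
  expect_true(all(c("rmse", "r_squared") %in% names(res$metrics)))
  expect_gt(res$metrics$r_squared, 0.3)  # g1 carries real signal
})

test_that("inner-CV metrics are optimistically biased relative to pooled metrics on noise", {
  d <- make_binary_data(50, 150, seed = 14)
  ds <- new_dataset(d$X, d$y)
  res <- tiny_nestcv(ds, seed = 6, k = 5, l = 3,
                     filter = filter_spec("ttest", n_keep = 30))
  expect_gt(res$inner_cv_metrics$auc, res$metrics$auc)
})

test_that("the final model follows the whole-data recipe and predicts by name", {
  d <- make_signal_data(50, 30, seed = 15)
  ds <- new_dataset(d$X, d$y)
  plan <- make_fold_plan(ds$y, 4, 3, seed = 3)
  res <- nestcv_fit(ds, plan, filter = filter_spec("ttest", n_keep = 10),
                    learner = small_en(), final = TRUE)
  expect_s3_class(res$final, "final_model")
  expect_equal(nrow(res$final$filter$kept), 10)

  p0 <- predict(res, ds$X)
  expect_length(p0, 50)
  # permuted columns: identical (name-based alignment)
  perm <- ds$X[, sample(ncol(ds$X))]
  expect_equal(predict(res, perm), p0)
  # missing selected predictor: error naming it
  sel <- res$final$predictor_names[1]
  expect_error(predict(res, ds$X[, setdiff(colnames(ds$X), sel)]), sel)
})

test_that("finalize with keep-all filter and one-point grid is a plain fit", {
  d <- make_binary_data(40, 10, seed = 16)
  ds <- new_dataset(d$X, d$y)
  learner <- elastic_net_learner(alpha = 1, lambda = 0.05)
  bundle <- finalize(ds, l_inner = 3, learner = learner, seed = 1)
  direct <- nestfold:::nf_fit(learner, ds$X, ds$y,
                              nestfold:::nf_fixed_params(learner), seed = 1)
  expect_equal(predict_new(bundle, ds$X), predict_scores(direct, ds$X),
               tolerance = 1e-12)
})

test_that("fold failures carry fold index and stage context", {
  d <- make_binary_data(30, 10, seed = 17)
  ds <- new_dataset(d$X, d$y)
  plan <- make_fold_plan(ds$y, 3, 2, seed = 1)
  boom <- filter_spec("custom", n_keep = 5,
                      fn = function(X, y, n_keep, seed, ...) stop("kaboom"))
  err <- tryCatch(nestcv_fit(ds, plan, filter = boom, learner = small_en()),
                  error = identity)
  expect_s3_class(err, "nestfold_fold_error")
  expect_match(conditionMessage(err), "outer fold 1")
  expect_match(conditionMessage(err), "stage 'filter'")
})

test_that("training-fold median imputation fills missing values", {
  d <- make_binary_data(40, 12, seed = 18)
  withr::with_seed(18,
    d$X[cbind(sample(40, 8), sample(12, 8, replace = TRUE))] <- NA)
  ds <- new_dataset(d$X, d$y, allow_missing = TRUE)
  plan <- make_fold_plan(ds$y, 3, 2, seed = 1)
  res <- nestcv_fit(ds, plan, filter = filter_spec("ttest", n_keep = 6),
                    learner = small_en(), impute = "median", final = FALSE)
  expect_false(anyNA(res$pooled$score))
  # default policy rejects missing values at construction
  expect_error(new_dataset(d$X, d$y), class = "nestfold_contract_violation")
})
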