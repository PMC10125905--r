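#' Fully nested cross-validation with embedded filtering and balancing
#'
#' For each outer fold, in this exact order: (1) take the outer training
#' rows; (2) apply class balancing (if any) to those rows only; (3) run
#' the feature filter on the balanced training rows; (4) tune
#' hyperparameters by inner CV on the balanced, filtered training rows;
#' (5) fit on the whole balanced, filtered outer training fold; (6)
#' predict the untouched, unbalanced outer test rows restricted to the
#' selected predictors. Out-of-fold test scores are pooled across outer
#' folds — every sample is scored exactly once — and summarised, and a
#' final model is fitted on the whole dataset by the same recipe.
#'
#' No stage ever sees outer-test-fold data before step (6): that is the
#' leakage-freedom contract this design exists for.
#'
#' @param dataset An [nf_dataset][new_dataset()] (or anything
#'   [as_dataset()] accepts together with `outcome`).
#' @param plan A [fold_plan][make_fold_plan()] matching the dataset size.
#' @param filter A [filter_spec()], or `NULL` to keep all predictors.
#' @param balance A [balance_spec()], or `NULL` for none (classification
#'   only).
#' @param learner An `nf_learner` (default [elastic_net_learner()]).
#' @param cores Workers for the outer loop (forked via
#'   `parallel::mclapply`; results are identical for any worker count
#'   because each fold uses a seed derived from the plan seed).
#' @param impute `"none"` (default; missing values are an error) or
#'   `"median"`: per fold, training-column medians imputed into training
#'   and test rows — never computed on the whole data.
#' @param final Also fit the final whole-data model (default TRUE).
#' @return A `nestcv_result`: `fold_records` (per-fold balance summary,
#'   `filter_result`, `tuned_learner`, model, test indices and scores),
#'   `pooled` (tibble of sample, fold, truth, score), `metrics`,
#'   `inner_cv_metrics` (the optimistically biased inner-CV estimate, when
#'   the learner tunes), `roc`, `final` (final-model bundle) and `plan`.
#' @seealso [outercv_fit()] for tuning-free learners, [finalize()] for the
#'   final-model recipe, [predict.nestcv_result()] for new data.
#' @export
nestcv_fit <- function(dataset, plan, filter = NULL, balance = NULL,
                       learner = elastic_net_learner(), cores = 1L,
                       impute = c("none", "median"), final = TRUE) {
  impute <- match.arg(impute)
  ds <- dataset
  if (!inherits(ds, "nf_dataset")) {
    abort_contract("dataset must be an nf_dataset; see as_dataset()")
  }
  if (plan$n_samples != nrow(ds$X)) {
    abort_contract("fold plan size does not match the dataset")
  }
  check_engine_specs(ds, filter, balance)

  records <- run_outer_loop(ds, plan, filter, balance, learner, cores,
                            impute, use_inner = TRUE)
  out <- collate_result(ds, plan, records, learner)
  if (final) {
    out$final <- finalize(ds, l_inner = plan$l_inner, filter = filter,
                          balance = balance, learner = learner,
                          seed = derive_seed(plan$seed, plan$k_outer + 1L),
                          stratify = plan$stratify, impute = impute)
  }
  out
}

#' Nested cross-validation from a data frame
#'
#' Tidy front end to [nestcv_fit()]: builds the dataset and fold plan and
#' runs the engine.
#'
#' @inheritParams as_dataset
#' @inheritParams nestcv_fit
#' @param k_outer,l_inner Outer and inner fold counts (default 10 x 10).
#' @param seed Integer seed controlling folds and all stochastic stages.
#' @param stratify Stratify folds (default TRUE).
#' @return A `nestcv_result`.
#' @export
nestcv <- function(data, outcome, k_outer = 10L, l_inner = 10L,
                   filter = NULL, balance = NULL,
                   learner = elastic_net_learner(), seed = 1L,
                   stratify = TRUE, cores = 1L,
                   impute = c("none", "median")) {
  ds <- as_dataset(data, outcome, allow_missing = match.arg(impute) == "median")
  plan <- make_fold_plan(ds$y, k_outer, l_inner, seed = seed,
                         stratify = stratify)
  nestcv_fit(ds, plan, filter = filter, balance = balance, learner = learner,
             cores = cores, impute = impute)
}

#' Outer-only cross-validation for tuning-free learners
#'
#' Performance measurement without the inner tuning loop: feature
#' filtering (and balancing) are still nested inside the outer CV loop,
#' but step (4) is skipped and the learner's fixed hyperparameters are
#' used directly. Only learners that declare themselves tuning-free are
#' accepted (e.g. a random forest with a fixed tree count, or an elastic
#' net with a single fixed alpha and lambda).
#'
#' @inheritParams nestcv_fit
#' @param k_outer Number of outer folds.
#' @param seed Integer seed for folds and stochastic stages.
#' @param stratify Stratify folds (default TRUE).
#' @param l_inner Inner fold count used only by the final-model tuning
#'   step (default 10).
#' @return A `nestcv_result` (with no inner-CV metrics).
#' @export
outercv_fit <- function(dataset, k_outer = 10L, filter = NULL,
                        learner = rf_learner(), balance = NULL, seed = 1L,
                        stratify = TRUE, cores = 1L,
                        impute = c("none", "median"), final = TRUE,
                        l_inner = 10L) {
  impute <- match.arg(impute)
  ds <- dataset
  if (!inherits(ds, "nf_dataset")) {
    abort_contract("dataset must be an nf_dataset; see as_dataset()")
  }
  if (!isTRUE(learner$tuning_free)) {
    abort_contract("outercv requires a tuning-free learner (fixed hyperparameters)")
  }
  check_engine_specs(ds, filter, balance)
  plan <- make_fold_plan(ds$y, k_outer, l_inner = 2L, seed = seed,
                         stratify = stratify)
  plan$l_inner <- as.integer(l_inner)  # only the finalize step tunes
  records <- run_outer_loop(ds, plan, filter, balance, learner, cores,
                            impute, use_inner = FALSE)
  out <- collate_result(ds, plan, records, learner)
  if (final) {
    out$final <- finalize(ds, l_inner = l_inner, filter = filter,
                          balance = balance, learner = learner,
                          seed = derive_seed(seed, k_outer + 1L),
                          stratify = stratify, impute = impute)
  }
  out
}

#' @rdname outercv_fit
#' @inheritParams nestcv
#' @export
outercv <- function(data, outcome, k_outer = 10L, filter = NULL,
                    learner = rf_learner(), balance = NULL, seed = 1L,
                    stratify = TRUE, cores = 1L,
                    impute = c("none", "median")) {
  ds <- as_dataset(data, outcome, allow_missing = match.arg(impute) == "median")
  outercv_fit(ds, k_outer = k_outer, filter = filter, learner = learner,
              balance = balance, seed = seed, stratify = stratify,
              cores = cores, impute = impute)
}

check_engine_specs <- function(ds, filter, balance) {
  if (ds$outcome_type == "multiclass") {
    abort_contract("the engine supports binary classification or regression outcomes")
  }
  if (!is.null(balance) && balance$method != "none" &&
      ds$outcome_type == "gaussian") {
    nf_abort("balancing is refused for regression outcomes",
             "nestfold_balance_regression")
  }
  if (!is.null(filter) && !inherits(filter, "filter_spec")) {
    abort_contract("filter must be a filter_spec()")
  }
  if (!is.null(balance) && !inherits(balance, "balance_spec")) {
    abort_contract("balance must be a balance_spec()")
  }
}

# one outer fold, as a pure function of (dataset, plan, specs, fold seed)
run_outer_fold <- function(i, ds, plan, filter, balance, learner, impute,
                           use_inner) {
  fold_seed <- derive_seed(plan$seed, i)
  test_idx <- plan$outer_folds[[i]]
  train_idx <- setdiff(seq_len(plan$n_samples), test_idx)
  Xtr <- ds$X[train_idx, , drop = FALSE]
  ytr <- ds$y[train_idx]
  Xte <- ds$X[test_idx, , drop = FALSE]

  stage <- "impute"
  res <- tryCatch({
    if (impute == "median") {
      med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
      Xtr <- impute_with(Xtr, med)
      Xte <- impute_with(Xte, med)
    }
    stage <- "balance"
    bal <- apply_balance(Xtr, ytr, balance, seed = fold_seed)
    rebalanced <- nrow(bal$X) != nrow(Xtr)

    stage <- "filter"
    fr <- if (is.null(filter)) NULL else run_filter(bal$X, bal$y, filter,
                                                    seed = fold_seed)
    Xf <- if (is.null(fr)) bal$X else apply_filter(bal$X, fr)

    stage <- "tune"
    inner <- if (!use_inner) {
      NULL
    } else if (rebalanced) {
      # balanced rows no longer match the plan's precomputed inner sets;
      # re-stratify on the balanced outcome with the fold-derived seed
      make_stratified_folds(bal$y, plan$l_inner, seed = fold_seed,
                            stratify = plan$stratify)
    } else {
      inner_positions(plan, i)
    }
    tuned <- nf_tune(learner, Xf, bal$y, inner, seed = fold_seed)

    stage <- "fit"
    model <- nf_fit(learner, Xf, bal$y, tuned, seed = fold_seed)

    stage <- "predict"
    Xte_f <- if (is.null(fr)) Xte else apply_filter(Xte, fr)
    scores <- predict_scores(model, Xte_f)

    list(fold = i, seed = fold_seed, test_idx = test_idx,
         balance_summary = bal$summary, filter = fr, tuned = tuned,
         model = model, scores = scores,
         inner_truth = if (!is.null(tuned$inner_scores)) bal$y,
         inner_scores = tuned$inner_scores)
  }, nestfold_error = function(e) e, error = function(e) e)
  if (inherits(res, "error")) {
    nf_abort(sprintf("outer fold %d failed at stage '%s': %s", i, stage,
                     conditionMessage(res)),
             "nestfold_fold_error")
  }
  res
}

impute_with <- function(X, medians) {
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- medians[nas[, 2L]]
  X
}

run_outer_loop <- function(ds, plan, filter, balance, learner, cores,
                           impute, use_inner) {
  worker <- function(i) run_outer_fold(i, ds, plan, filter, balance,
                                       learner, impute, use_inner)
  if (cores > 1L) {
    res <- parallel::mclapply(seq_len(plan$k_outer), worker,
                              mc.cores = cores, mc.preschedule = TRUE)
    errs <- vapply(res, inherits, logical(1), "try-error")
    if (any(errs)) {
      nf_abort(paste0("parallel outer fold failed: ",
                      attr(res[[which(errs)[1L]]], "condition")$message),
               "nestfold_fold_error")
    }
    res
  } else {
    lapply(seq_len(plan$k_outer), worker)
  }
}

collate_result <- function(ds, plan, records, learner) {
  n <- plan$n_samples
  scores <- rep(NA_real_, n)
  fold_of <- rep(NA_integer_, n)
  for (rec in records) {
    scores[rec$test_idx] <- rec$scores
    fold_of[rec$test_idx] <- rec$fold
  }
  if (anyNA(scores)) {
    nf_abort("pooling incomplete: some samples were never scored",
             "nestfold_contract_violation")
  }
  classification <- ds$outcome_type == "binomial"
  pooled <- tibble::tibble(
    sample_id = ds$sample_ids, fold = fold_of,
    truth = ds$y, score = scores)
  metrics <- if (classification) {
    classification_summary(scores, ds$y)
  } else {
    regression_summary(scores, ds$y)
  }
  roc <- if (classification) roc_curve(scores, ds$y)
  inner_metrics <- inner_cv_metrics(records, classification)

  structure(
    list(fold_records = records, pooled = pooled, metrics = metrics,
         inner_cv_metrics = inner_metrics, roc = roc, plan = plan,
         learner = learner$name,
         outcome_type = ds$outcome_type,
         positive_class = if (classification) positive_class(ds$y),
         final = NULL),
    class = "nestcv_result")
}

# pooled performance on inner left-out folds at each fold's chosen
# hyperparameters: optimistically biased, reported for comparison only
inner_cv_metrics <- function(records, classification) {
  sc <- unlist(lapply(records, `[[`, "inner_scores"))
  if (is.null(sc) || !length(sc)) return(NULL)
  tr <- unlist(lapply(records, function(r) as.character(r$inner_truth)))
  if (classification) {
    classification_summary(sc, factor(tr))
  } else {
    regression_summary(sc, as.numeric(tr))
  }
}

#' Fit the final whole-data model
#'
#' The final model follows the same recipe as each outer training fold,
#' applied to the whole dataset: (1) filter predictors on the whole data;
#' (2) optionally balance; (3) tune hyperparameters by fresh seeded
#' `l_inner`-fold CV on the whole data; (4) fit the tuned model to the
#' whole data. By construction its filter sees all rows — it is the
#' deployable model, not the performance estimate.
#'
#' @inheritParams nestcv_fit
#' @param l_inner Fold count for the tuning CV (default 10).
#' @param seed Integer seed for balancing/tuning folds.
#' @param stratify Stratify the tuning folds.
#' @return A `final_model` bundle: `filter`, `tuned`, `model`, and the
#'   predictor names it consumes.
#' @export
finalize <- function(dataset, l_inner = 10L, filter = NULL, balance = NULL,
                     learner = elastic_net_learner(), seed = 1L,
                     stratify = TRUE, impute = c("none", "median")) {
  impute <- match.arg(impute)
  ds <- dataset
  X <- ds$X
  if (impute == "median") {
    med <- apply(X, 2, stats::median, na.rm = TRUE)
    X <- impute_with(X, med)
  }
  fr <- if (is.null(filter)) NULL else run_filter(X, ds$y, filter,
                                                  seed = seed)
  bal <- apply_balance(X, ds$y, balance, seed = seed)
  Xf <- if (is.null(fr)) bal$X else apply_filter(bal$X, fr)
  inner <- if (isTRUE(learner$tuning_free)) {
    NULL
  } else {
    make_stratified_folds(bal$y, l_inner, seed = seed, stratify = stratify)
  }
  tuned <- nf_tune(learner, Xf, bal$y, inner, seed = seed)
  model <- nf_fit(learner, Xf, bal$y, tuned, seed = seed)
  structure(
    list(filter = fr, tuned = tuned, model = model,
         balance_summary = bal$summary,
         predictor_names = model$predictor_names,
         outcome_type = ds$outcome_type,
         positive_class = if (is.factor(ds$y)) positive_class(ds$y)),
    class = "final_model")
}

#' Predict from a final model bundle on new data
#'
#' Applies the stored filter's column selection *by predictor name*, then
#' the fitted model, so new data may carry extra columns in any order.
#' Missing selected predictors raise an error naming them.
#'
#' @param bundle A `final_model` from [finalize()] (or
#'   `result$final`).
#' @param newdata Matrix or data frame of new samples with named columns.
#' @return Numeric score vector (positive-class probability for
#'   classification).
#' @export
predict_new <- function(bundle, newdata) {
  if (!inherits(bundle, "final_model")) {
    abort_contract("bundle must be a final_model")
  }
  X <- as.matrix(newdata)
  predict_scores(bundle$model, X)
}

#' @export
predict.nestcv_result <- function(object, newdata, ...) {
  if (is.null(object$final)) {
    abort_contract("this result has no final model; rerun with final = TRUE")
  }
  predict_new(object$final, newdata)
}

#' @export
print.nestcv_result <- function(x, ...) {
  cat(sprintf("<nestcv_result> %s, %d outer folds, %d samples\n",
              x$learner, x$plan$k_outer, x$plan$n_samples))
  cat("Pooled out-of-fold metrics (unbiased):\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  if (!is.null(x$inner_cv_metrics)) {
    cat("Inner-CV metrics (optimistically biased; comparison only):\n")
    print(as.data.frame(x$inner_cv_metrics), row.names = FALSE)
  }
  if (!is.null(x$positive_class)) {
    cat(sprintf("Positive class: %s\n", x$positive_class))
  }
  invisible(x)
}

#' @export
summary.nestcv_result <- function(object, ...) {
  print(object)
  cat("\nPer-fold summary:\n")
  print(as.data.frame(fold_table(object)), row.names = FALSE)
  invisible(object)
}

# per-fold report: fold, n selected, tuned params, fold AUC / RMSE
fold_table <- function(result) {
  classification <- result$outcome_type == "binomial"
  purrr::map_dfr(result$fold_records, function(rec) {
    params <- rec$tuned$params
    truth <- result$pooled$truth[rec$test_idx]
    perf <- if (classification) {
      if (length(unique(truth)) > 1L) roc_auc(rec$scores, truth) else NA_real_
    } else {
      sqrt(mean((rec$scores - truth)^2))
    }
    tibble::tibble(
      fold = rec$fold,
      n_selected = if (is.null(rec$filter)) NA_integer_ else nrow(rec$filter$kept),
      alpha = params$alpha %||% NA_real_,
      lambda = params$lambda %||% NA_real_,
      fold_metric = perf)
  })
}

#' Export a nested-CV run's report files
#'
#' Writes `metrics.json` (pooled and inner-CV metrics, positive class),
#' `folds.tsv` (fold, n selected, tuned alpha/lambda, fold metric),
#' `predictions.tsv` (sample id, outer fold, truth, score), `roc.tsv`
#' (classification only), and `importance.tsv` (final model).
#'
#' @param result A `nestcv_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_files <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- list(
    learner = result$learner,
    outcome_type = result$outcome_type,
    positive_class = result$positive_class,
    pooled = as.list(result$metrics),
    inner_cv = if (!is.null(result$inner_cv_metrics))
      as.list(result$inner_cv_metrics))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_tsv(fold_table(result), file.path(dir, "folds.tsv"))
  readr::write_tsv(result$pooled, file.path(dir, "predictions.tsv"))
  if (!is.null(result$roc)) write_roc_tsv(result$roc, file.path(dir, "roc.tsv"))
  if (!is.null(result$final)) {
    imp <- variable_importance(result$final$model)
    readr::write_tsv(imp, file.path(dir, "importance.tsv"))
  }
  invisible(dir)
}
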