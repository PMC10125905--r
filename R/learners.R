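#' Elastic-net learner with inner-CV tuning of alpha and lambda
#'
#' Defines an elastic net (via glmnet) whose mixing parameter `alpha` and
#' penalty `lambda` are tuned on inner CV folds. One shared lambda path
#' per alpha is computed on the full training fold from the data maximum
#' (the smallest lambda nulling all coefficients at that alpha); ridge
#' (`alpha = 0`) has no finite nulling lambda, so its path maximum is
#' 1000 x the `alpha = 0.001` path maximum. Supplying a single `alpha`
#' together with a single fixed `lambda` makes the learner tuning-free
#' (usable with [outercv()]).
#'
#' @param alpha Grid of mixing values in `[0, 1]`; default
#'   `c(0, 0.25, 0.5, 0.75, 1)`.
#' @param lambda Optional fixed lambda value(s); `NULL` (default) builds a
#'   path per alpha.
#' @param n_lambda Path length per alpha (default 100).
#' @param lambda_min_ratio Smallest/largest lambda on the path; default
#'   `1e-3` when `n > P`, else `1e-2`.
#' @param metric Inner-CV tuning metric: `"deviance"` (default, binomial
#'   deviance) or `"auc"` for classification; regression always uses MSE.
#' @return An object of class `c("en_learner", "nf_learner")`.
#' @export
elastic_net_learner <- function(alpha = c(0, 0.25, 0.5, 0.75, 1),
                                lambda = NULL, n_lambda = 100L,
                                lambda_min_ratio = NULL,
                                metric = c("deviance", "auc")) {
  metric <- match.arg(metric)
  if (any(alpha < 0 | alpha > 1)) abort_contract("alpha values must lie in [0, 1]")
  if (is.null(lambda) && n_lambda < 2L) abort_contract("n_lambda must be >= 2")
  structure(
    list(name = "elastic_net",
         alpha = sort(unique(alpha)),
         lambda = lambda,
         n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio,
         metric = metric,
         tuning_free = !is.null(lambda) &&
           length(lambda) == 1L && length(unique(alpha)) == 1L),
    class = c("en_learner", "nf_learner"))
}

#' Random forest learner with fixed hyperparameters
#'
#' A tuning-free learner (the number of trees does not require tuning
#' against test performance), intended for [outercv()] where only feature
#' filtering is nested inside the outer CV loop.
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Predictors sampled per split (default: ranger's default).
#' @return An object of class `c("rf_nf_learner", "nf_learner")`.
#' @export
rf_learner <- function(n_trees = 500L, mtry = NULL) {
  structure(list(name = "random_forest", n_trees = as.integer(n_trees),
                 mtry = mtry, tuning_free = TRUE),
            class = c("rf_nf_learner", "nf_learner"))
}

#' Wrap user-supplied tune/fit/predict functions as a learner
#'
#' Any object satisfying the tune/fit/predict contract can be swapped into
#' the engine. `fit(X, y, params, seed)` must return a model,
#' `predict(model, X)` a score vector (positive-class probability for
#' classification), and `tune(X, y, inner_folds, seed)`, when supplied, a
#' list with at least `params`; omit `tune` for tuning-free learners.
#'
#' @param fit,predict,tune,importance Functions per the contract
#'   (`importance(model)` optional, returning a two-column data frame).
#' @param name Learner label used in reports.
#' @return An object of class `c("custom_nf_learner", "nf_learner")`.
#' @export
custom_learner <- function(fit, predict, tune = NULL, importance = NULL,
                           name = "custom") {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(name = name, fit_fn = fit, predict_fn = predict,
                 tune_fn = tune, importance_fn = importance,
                 tuning_free = is.null(tune)),
            class = c("custom_nf_learner", "nf_learner"))
}

en_family <- function(y) if (is.factor(y)) "binomial" else "gaussian"

en_lambda_path <- function(X, y, alpha, learner) {
  if (!is.null(learner$lambda)) return(sort(learner$lambda, decreasing = TRUE))
  lmr <- learner$lambda_min_ratio %||%
    (if (nrow(X) > ncol(X)) 1e-3 else 1e-2)
  a_eff <- max(alpha, 0.001)
  fit <- glmnet::glmnet(X, y, family = en_family(y), alpha = a_eff,
                        nlambda = 3L)
  lmax <- max(fit$lambda)
  if (alpha == 0) lmax <- lmax * 1000
  exp(seq(log(lmax), log(lmax * lmr), length.out = learner$n_lambda))
}

binomial_deviance <- function(p, y_pos) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(ifelse(y_pos, log(p), log(1 - p)))
}

# mean inner-CV score per (alpha, lambda); lower is better on the internal
# scale (-AUC is minimized when metric = "auc")
#' Tune an elastic net over alpha and lambda on inner CV folds
#'
#' Exhaustively evaluates every (alpha, lambda) grid point by fitting on
#' each inner training set and scoring on the inner left-out fold, then
#' returns the pair minimizing the mean tuning metric. Exact score ties
#' are broken toward larger lambda, then larger alpha (the sparser model).
#' Inner-fold predictions at the chosen pair are retained: pooled, they
#' give the optimistically biased inner-CV performance estimate.
#'
#' @param X Training matrix (already balanced/filtered by the engine).
#' @param y Training outcome.
#' @param inner_folds List of >= 2 disjoint index sets partitioning
#'   `1:nrow(X)`.
#' @param learner An [elastic_net_learner()].
#' @return A `tuned_learner`: chosen `params` (`alpha`, `lambda`), the
#'   full `score_table` (tibble alpha, lambda, score), the tuning
#'   `metric`, and inner out-of-fold predictions.
#' @export
tune_elastic_net <- function(X, y, inner_folds,
                             learner = elastic_net_learner()) {
  if (length(inner_folds) < 2L) abort_fold_count("need >= 2 inner folds")
  idx_all <- sort(unlist(inner_folds))
  if (!identical(idx_all, seq_len(nrow(X)))) {
    abort_contract("inner folds must partition the training rows")
  }
  family <- en_family(y)
  classification <- family == "binomial"
  if (classification && nlevels(droplevels(y)) < 2L) {
    abort_degenerate("training outcome has a single class")
  }
  # single-class inner *training* sets cannot fit a binomial model
  if (classification) {
    bad <- vapply(inner_folds, function(f)
      nlevels(droplevels(y[-f])) < 2L, logical(1))
    if (any(bad)) abort_degenerate("an inner training set has a single class; re-stratify inner folds")
  }
  paths <- lapply(learner$alpha, function(a) en_lambda_path(X, y, a, learner))
  n_a <- length(learner$alpha)
  score_folds <- vector("list", n_a)   # [alpha][lambda x fold]
  pred_folds <- vector("list", n_a)    # inner oof predictions per alpha
  for (ai in seq_len(n_a)) {
    a <- learner$alpha[ai]
    lam <- paths[[ai]]
    sc <- matrix(NA_real_, length(lam), length(inner_folds))
    pr <- matrix(NA_real_, nrow(X), length(lam))
    for (fi in seq_along(inner_folds)) {
      hold <- inner_folds[[fi]]
      fit <- glmnet::glmnet(X[-hold, , drop = FALSE], y[-hold],
                            family = family, alpha = a, lambda = lam)
      p <- stats::predict(fit, X[hold, , drop = FALSE], s = lam,
                          type = "response")
      pr[hold, ] <- p
      if (classification) {
        y_pos <- y[hold] == positive_class(y)
        sc[, fi] <- if (learner$metric == "auc") {
          apply(p, 2, function(col) {
            if (length(unique(y_pos)) < 2L) return(NA_real_)
            -roc_auc(col, y[hold])
          })
        } else {
          apply(p, 2, binomial_deviance, y_pos = y_pos)
        }
      } else {
        sc[, fi] <- colMeans((p - y[hold])^2)
      }
    }
    score_folds[[ai]] <- rowMeans(sc, na.rm = TRUE)
    pred_folds[[ai]] <- pr
  }
  tab <- tibble::tibble(
    alpha = rep(learner$alpha, lengths(paths)),
    lambda = unlist(paths),
    score = unlist(score_folds))
  best_score <- min(tab$score)
  ties <- which(tab$score == best_score)
  best <- ties[order(-tab$lambda[ties], -tab$alpha[ties])][1L]
  ai <- match(tab$alpha[best], learner$alpha)
  li <- match(tab$lambda[best], paths[[ai]])
  metric_name <- if (classification) learner$metric else "mse"
  structure(
    list(learner = "elastic_net",
         params = list(alpha = tab$alpha[best], lambda = tab$lambda[best]),
         score = best_score,
         metric = metric_name,
         score_table = tab,
         lambda_paths = stats::setNames(paths, learner$alpha),
         inner_scores = pred_folds[[ai]][, li],
         config = learner),
    class = "tuned_learner")
}

#' @export
print.tuned_learner <- function(x, ...) {
  cat(sprintf("<tuned_learner> %s: %s | inner-CV %s = %.4g\n", x$learner,
              paste(names(x$params),
                    signif(unlist(x$params), 4), sep = "=", collapse = ", "),
              x$metric, abs(x$score)))
  invisible(x)
}

# ---- generic learner contract used by the engine ------------------------

nf_tune <- function(learner, X, y, inner_folds, seed) UseMethod("nf_tune")

#' @export
nf_tune.en_learner <- function(learner, X, y, inner_folds, seed) {
  if (is.null(inner_folds)) {
    if (!learner$tuning_free) {
      abort_contract("this elastic net needs inner folds for tuning; give a single alpha and fixed lambda for outer-only CV")
    }
    return(nf_fixed_params(learner))
  }
  tune_elastic_net(X, y, inner_folds, learner)
}

#' @export
nf_tune.rf_nf_learner <- function(learner, X, y, inner_folds, seed) {
  nf_fixed_params(learner)
}

#' @export
nf_tune.custom_nf_learner <- function(learner, X, y, inner_folds, seed) {
  if (learner$tuning_free || is.null(inner_folds)) {
    if (!learner$tuning_free) {
      abort_contract("this custom learner needs inner folds for tuning")
    }
    return(nf_fixed_params(learner))
  }
  res <- learner$tune_fn(X, y, inner_folds, seed)
  structure(list(learner = learner$name, params = res$params,
                 score = res$score %||% NA_real_,
                 metric = res$metric %||% "custom",
                 score_table = res$score_table,
                 inner_scores = res$inner_scores, config = learner),
            class = "tuned_learner")
}

# fixed-parameter learners skip inner CV entirely
nf_fixed_params <- function(learner) {
  params <- switch(class(learner)[1L],
    en_learner = list(alpha = learner$alpha, lambda = learner$lambda),
    rf_nf_learner = list(n_trees = learner$n_trees, mtry = learner$mtry),
    list())
  structure(list(learner = learner$name, params = params, score = NA_real_,
                 metric = "fixed", score_table = NULL, inner_scores = NULL,
                 config = learner),
            class = "tuned_learner")
}

nf_fit <- function(learner, X, y, tuned, seed) UseMethod("nf_fit")

#' @export
nf_fit.en_learner <- function(learner, X, y, tuned, seed) {
  lam <- tuned$params$lambda
  path <- if (!is.null(tuned$lambda_paths)) {
    tuned$lambda_paths[[as.character(tuned$params$alpha)]]
  } else lam
  fit <- glmnet::glmnet(X, y, family = en_family(y),
                        alpha = tuned$params$alpha, lambda = path)
  structure(
    list(fit = fit, alpha = tuned$params$alpha, lambda = lam,
         predictor_names = colnames(X),
         x_sd = apply(X, 2, stats::sd),
         classes = if (is.factor(y)) levels(y),
         family = en_family(y)),
    class = "en_model")
}

#' @export
nf_fit.rf_nf_learner <- function(learner, X, y, tuned, seed) {
  classification <- is.factor(y)
  fit <- ranger::ranger(
    x = as.data.frame(X), y = y, num.trees = learner$n_trees,
    mtry = learner$mtry, probability = classification,
    importance = "impurity", seed = seed, num.threads = 1L)
  structure(list(fit = fit, predictor_names = colnames(X),
                 classes = if (classification) levels(y)),
            class = "rf_model")
}

#' @export
nf_fit.custom_nf_learner <- function(learner, X, y, tuned, seed) {
  structure(list(fit = learner$fit_fn(X, y, tuned$params, seed),
                 predictor_names = colnames(X),
                 classes = if (is.factor(y)) levels(y),
                 learner = learner),
            class = "custom_model")
}

# align newdata columns to the model's training predictors by NAME
align_columns <- function(model, X) {
  want <- model$predictor_names
  have <- colnames(X)
  if (is.null(have)) {
    abort_contract("prediction matrix must carry predictor names")
  }
  missing <- setdiff(want, have)
  if (length(missing)) {
    abort_contract(paste0("prediction matrix is missing predictors: ",
                          paste(utils::head(missing, 10), collapse = ", ")))
  }
  X[, want, drop = FALSE]
}

#' Predict scores from a fitted model
#'
#' Classification models return the probability of the positive class (the
#' second outcome level); regression models return real-valued
#' predictions. Columns of `X` are aligned to the training predictors by
#' name, so column order is irrelevant; missing predictors are an error.
#'
#' @param model A fitted model from the engine (`en_model`, `rf_model`, or
#'   a custom model).
#' @param X Matrix of new samples (columns named as at training).
#' @return Numeric score vector, one value per row of `X`.
#' @export
predict_scores <- function(model, X) UseMethod("predict_scores")

#' @export
predict_scores.en_model <- function(model, X) {
  X <- align_columns(model, X)
  as.vector(stats::predict(model$fit, X, s = model$lambda,
                           type = "response"))
}

#' @export
predict_scores.rf_model <- function(model, X) {
  X <- align_columns(model, X)
  pr <- stats::predict(model$fit, data = as.data.frame(X),
                       num.threads = 1L)$predictions
  if (!is.null(model$classes)) pr[, model$classes[2L]] else as.vector(pr)
}

#' @export
predict_scores.custom_model <- function(model, X) {
  X <- align_columns(model, X)
  model$learner$predict_fn(model$fit, X)
}

#' Variable importance of a fitted model
#'
#' Elastic net: absolute standardized coefficient (|beta_j| x sd(x_j), the
#' coefficient on the standardized scale) for each retained predictor.
#' Random forest: impurity importance. Sorted descending.
#'
#' @param model A fitted model.
#' @return Tibble with `predictor` and `importance`, best first.
#' @export
variable_importance <- function(model) UseMethod("variable_importance")

#' @export
variable_importance.en_model <- function(model) {
  co <- stats::coef(model$fit, s = model$lambda)
  beta <- as.vector(co)[-1L]
  names(beta) <- rownames(co)[-1L]
  imp <- abs(beta) * model$x_sd[names(beta)]
  imp <- imp[beta != 0]
  tibble::tibble(predictor = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(importance))
}

#' @export
variable_importance.rf_model <- function(model) {
  imp <- model$fit$variable.importance
  tibble::tibble(predictor = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(importance))
}

#' @export
variable_importance.custom_model <- function(model) {
  fn <- model$learner$importance_fn
  if (is.null(fn)) {
    abort_contract("this custom learner does not provide importances")
  }
  tibble::as_tibble(fn(model$fit))
}
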