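#' Specify a feature filter
#'
#' A filter ranks predictors by association with the outcome *on training
#' rows only* and keeps the top `n_keep`. Built-in methods: `ttest`
#' (Welch, unequal variance), `wilcoxon` (standardized rank-sum with tie
#' correction), `anova` (one-way F), `pearson`/`spearman` correlation (for
#' continuous outcomes), `rf` (random forest impurity importance),
#' `relieff`, or `custom` (supply `fn(X, y, n_keep, seed, ...)` returning a
#' `filter_result`).
#'
#' @param method One of `"ttest"`, `"wilcoxon"`, `"anova"`, `"pearson"`,
#'   `"spearman"`, `"rf"`, `"relieff"`, `"custom"`.
#' @param n_keep Number of predictors to retain (>= 1).
#' @param ... Method parameters: `n_trees` (rf, default 500),
#'   `n_neighbors` (relieff, default 10), `n_samples_used` (relieff,
#'   default all), `fn` (custom).
#' @return A `filter_spec`.
#' @export
filter_spec <- function(method = c("ttest", "wilcoxon", "anova", "pearson",
                                   "spearman", "rf", "relieff", "custom"),
                        n_keep = 100L, ...) {
  method <- match.arg(method)
  params <- list(...)
  if (n_keep < 1L) abort_contract("n_keep must be at least 1")
  if (method == "custom" && !is.function(params$fn)) {
    abort_contract("custom filters require a function argument `fn`")
  }
  if (method == "rf") params$n_trees <- as.integer(params$n_trees %||% 500L)
  if (method == "relieff") {
    params$n_neighbors <- as.integer(params$n_neighbors %||% 10L)
    if (params$n_neighbors < 1L) abort_contract("n_neighbors must be >= 1")
  }
  structure(list(method = method, n_keep = as.integer(n_keep),
                 params = params),
            class = "filter_spec")
}

# build a filter_result from raw per-predictor scores (NA = ineligible)
new_filter_result <- function(method, scores, n_keep, names = NULL,
                              dropped = integer()) {
  p <- length(scores)
  names <- names %||% paste0("V", seq_len(p))
  eligible <- setdiff(which(!is.na(scores)), dropped)
  if (n_keep > length(eligible)) {
    rlang::warn(sprintf(
      "n_keep (%d) exceeds eligible predictors (%d); keeping all eligible",
      n_keep, length(eligible)))
  }
  keep_n <- min(n_keep, length(eligible))
  ord <- eligible[order(-scores[eligible], eligible)]
  kept <- utils::head(ord, keep_n)
  structure(
    list(method = method,
         kept = tibble::tibble(rank = seq_along(kept), index = kept,
                               predictor = names[kept],
                               score = unname(scores[kept])),
         dropped_degenerate = sort(as.integer(dropped)),
         n_keep = as.integer(n_keep)),
    class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %s: %d predictors kept, %d degenerate dropped\n",
              x$method, nrow(x$kept), length(x$dropped_degenerate)))
  print(utils::head(x$kept, 5))
  invisible(x)
}

#' Ordered indices of the predictors a filter kept
#' @param result A `filter_result`.
#' @return Integer vector, best predictor first.
#' @export
kept_indices <- function(result) result$kept$index

check_binary_y <- function(y, min_per_class = 2L) {
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) abort_degenerate("outcome has a single class")
  if (nlevels(y) != 2L) abort_contract("a binary outcome is required")
  if (any(table(y) < min_per_class)) {
    abort_degenerate(sprintf("each class needs >= %d training samples",
                             min_per_class))
  }
  y
}

filter_names <- function(X) colnames(X) %||% paste0("V", seq_len(ncol(X)))

#' Welch t-test filter
#'
#' Ranks predictors by descending absolute Welch (unequal-variance)
#' t statistic between the two outcome classes; ties broken by ascending
#' predictor index. Predictors with zero variance in both groups have an
#' undefined statistic and are reported in `dropped_degenerate`.
#'
#' @param X Numeric training matrix (samples x predictors).
#' @param y Binary outcome for the training rows.
#' @param n_keep Number of predictors to keep.
#' @return A `filter_result`.
#' @export
ttest_filter <- function(X, y, n_keep = 100L) {
  y <- check_binary_y(y)
  g1 <- which(y == levels(y)[1L]); g2 <- which(y == levels(y)[2L])
  m1 <- colMeans(X[g1, , drop = FALSE]); m2 <- colMeans(X[g2, , drop = FALSE])
  v1 <- col_vars(X[g1, , drop = FALSE]); v2 <- col_vars(X[g2, , drop = FALSE])
  se2 <- v1 / length(g1) + v2 / length(g2)
  tt <- abs(m1 - m2) / sqrt(se2)
  dropped <- which(v1 == 0 & v2 == 0)
  tt[dropped] <- NA_real_
  new_filter_result("ttest", tt, n_keep, filter_names(X), dropped)
}

#' Wilcoxon rank-sum filter
#'
#' Ranks predictors by descending absolute standardized rank-sum statistic
#' (normal approximation with tie correction). A predictor whose values are
#' all tied has statistic 0 and ranks last among eligible predictors.
#'
#' @inheritParams ttest_filter
#' @return A `filter_result`.
#' @export
wilcoxon_filter <- function(X, y, n_keep = 100L) {
  y <- check_binary_y(y)
  g1 <- y == levels(y)[1L]
  n <- length(y); n1 <- sum(g1); n2 <- n - n1
  z <- apply(X, 2, function(x) {
    r <- rank(x)
    W <- sum(r[g1])
    ties <- table(x)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(0)
    (W - n1 * (n + 1) / 2) / sqrt(sig2)
  })
  dropped <- which(col_vars(X) == 0)
  score <- abs(z)
  score[dropped] <- NA_real_
  new_filter_result("wilcoxon", score, n_keep, filter_names(X), dropped)
}

#' One-way ANOVA filter
#'
#' Ranks predictors by descending one-way F statistic across two or more
#' outcome classes. With two classes the ranking coincides with a pooled-
#' variance t-test (F = t^2).
#'
#' @param X Numeric training matrix.
#' @param y Categorical outcome with >= 2 classes, each with >= 2 members.
#' @param n_keep Number of predictors to keep.
#' @return A `filter_result`.
#' @export
anova_filter <- function(X, y, n_keep = 100L) {
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) abort_degenerate("outcome has a single class")
  if (any(table(y) < 2L)) {
    abort_degenerate("every class needs >= 2 members for one-way ANOVA")
  }
  n <- length(y); g <- nlevels(y)
  gm <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (cl in levels(y)) {
    idx <- which(y == cl)
    mcl <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (mcl - gm)^2
    ssw <- ssw + (length(idx) - 1L) * col_vars(X[idx, , drop = FALSE])
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))  # ssw 0, ssb > 0 -> Inf, ranks first
  dropped <- which(ssb == 0 & ssw == 0)
  f[dropped] <- NA_real_
  new_filter_result("anova", f, n_keep, filter_names(X), dropped)
}

#' Correlation filter for continuous outcomes
#'
#' Ranks predictors by descending absolute Pearson or Spearman correlation
#' with a continuous outcome (Spearman = Pearson on ranks).
#'
#' @param X Numeric training matrix.
#' @param y Continuous outcome.
#' @param n_keep Number of predictors to keep.
#' @param kind `"pearson"` or `"spearman"`.
#' @return A `filter_result`.
#' @export
correlation_filter <- function(X, y, n_keep = 100L,
                               kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  if (stats::var(y) == 0) abort_degenerate("outcome has zero variance")
  r <- suppressWarnings(as.vector(stats::cor(X, y, method = kind)))
  dropped <- which(is.na(r))
  new_filter_result(kind, abs(r), n_keep, filter_names(X), dropped)
}

#' Random forest variable importance filter
#'
#' Ranks predictors by descending impurity-based importance from a seeded
#' random forest grown on the training rows only.
#'
#' @inheritParams ttest_filter
#' @param y Outcome (factor for classification, numeric for regression).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed for the forest.
#' @return A `filter_result`.
#' @export
rf_importance_filter <- function(X, y, n_keep = 100L, n_trees = 500L,
                                 seed = 1L) {
  if (is.character(y) || is.logical(y)) y <- factor(y)
  dropped <- which(col_vars(X) == 0)
  nm <- filter_names(X)
  colnames(X) <- nm
  fit <- tryCatch(
    ranger::ranger(x = as.data.frame(X), y = y, num.trees = n_trees,
                   importance = "impurity", seed = seed, num.threads = 1L),
    error = function(e) nf_abort(paste0("random forest filter failed: ",
                                        conditionMessage(e)),
                                 "nestfold_filter_error"))
  imp <- fit$variable.importance[nm]
  imp[dropped] <- NA_real_
  new_filter_result("rf", unname(imp), n_keep, nm, dropped)
}

#' ReliefF filter
#'
#' Multi-class ReliefF: for `n_samples_used` sampled instances, each
#' predictor's weight is decreased by its mean Manhattan distance (on
#' min-max scaled features) to the instance's `n_neighbors` nearest hits
#' and increased by the class-prior-weighted mean distance to the nearest
#' misses of every other class. Neighbor search is exhaustive. Predictors
#' identical across samples receive weight exactly 0.
#'
#' @inheritParams ttest_filter
#' @param y Binary or categorical outcome.
#' @param n_neighbors Nearest hits/misses per class (default 10; classes
#'   with fewer members use all available, with a warning).
#' @param n_samples_used Instances sampled for the update loop (default:
#'   all samples).
#' @param seed Integer seed for instance sampling.
#' @return A `filter_result`.
#' @export
relieff_filter <- function(X, y, n_keep = 100L, n_neighbors = 10L,
                           n_samples_used = NULL, seed = 1L) {
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) abort_degenerate("outcome has a single class")
  w <- relieff_weights(X, y, n_neighbors,
                       n_samples_used %||% nrow(X), seed)
  dropped <- which(col_vars(X) == 0)
  w[dropped] <- NA_real_
  new_filter_result("relieff", w, n_keep, filter_names(X), dropped)
}

relieff_weights <- function(X, y, n_neighbors, n_samples_used, seed) {
  n <- nrow(X); p <- ncol(X)
  lo <- apply(X, 2, min); span <- apply(X, 2, max) - lo
  span[span == 0] <- 1  # constant features scale to 0 everywhere -> diff 0
  Xs <- sweep(sweep(X, 2, lo), 2, span, "/")
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  prior <- table(y) / n
  m <- min(n_samples_used, n)
  sampled <- withr::with_seed(seed, sample(n, m))
  W <- numeric(p)
  warned <- FALSE
  for (i in sampled) {
    for (cl in levels(y)) {
      members <- which(y == cl)
      members <- members[members != i]
      if (!length(members)) next
      k_use <- min(n_neighbors, length(members))
      if (k_use < n_neighbors && !warned) {
        rlang::warn("a class has fewer members than n_neighbors; using all available")
        warned <- TRUE
      }
      ord <- members[order(D[i, members], members)]  # stable ties by index
      nn <- ord[seq_len(k_use)]
      dif <- colMeans(abs(Xs[nn, , drop = FALSE] -
                            rep(Xs[i, ], each = k_use)))
      if (cl == as.character(y[i])) {
        W <- W - dif / m
      } else {
        W <- W + as.numeric(prior[cl]) /
          (1 - as.numeric(prior[as.character(y[i])])) * dif / m
      }
    }
  }
  W
}

#' Subset a matrix to a filter's kept predictors
#'
#' Columns are subset and ordered as `kept_indices(result)`; row order is
#' unchanged. Applying a training-fold filter to the matching test fold is
#' the intended use.
#'
#' @param X Any matrix with the same column space the filter was run on.
#' @param result A `filter_result`.
#' @return The reduced matrix.
#' @export
apply_filter <- function(X, result) {
  idx <- kept_indices(result)
  if (length(idx) && (max(idx) > ncol(X) || min(idx) < 1L)) {
    abort_contract("filter indices out of range for this matrix")
  }
  X[, idx, drop = FALSE]
}

# engine-facing dispatcher
run_filter <- function(X, y, spec, seed = 1L) {
  switch(spec$method,
    ttest = ttest_filter(X, y, spec$n_keep),
    wilcoxon = wilcoxon_filter(X, y, spec$n_keep),
    anova = anova_filter(X, y, spec$n_keep),
    pearson = correlation_filter(X, y, spec$n_keep, "pearson"),
    spearman = correlation_filter(X, y, spec$n_keep, "spearman"),
    rf = rf_importance_filter(X, y, spec$n_keep,
                              n_trees = spec$params$n_trees, seed = seed),
    relieff = relieff_filter(X, y, spec$n_keep,
                             n_neighbors = spec$params$n_neighbors,
                             n_samples_used = spec$params$n_samples_used,
                             seed = seed),
    custom = {
      res <- do.call(spec$params$fn,
                     c(list(X = X, y = y, n_keep = spec$n_keep, seed = seed),
                       spec$params[setdiff(names(spec$params), "fn")]))
      if (!inherits(res, "filter_result")) {
        abort_contract("custom filter must return a filter_result")
      }
      res
    })
}

#' Write a filter result as TSV (rank, predictor, score)
#' @param result A `filter_result`.
#' @param path Output file path.
#' @export
write_filter_tsv <- function(result, path) {
  readr::write_tsv(result$kept[c("rank", "predictor", "score")], path)
  invisible(path)
}
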