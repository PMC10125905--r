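#' Stratified k-fold partition of sample indices
#'
#' Partitions `1:length(y)` into `k` disjoint folds. For classification
#' outcomes each class is shuffled with the seeded RNG and dealt
#' round-robin across folds, so per-class counts differ by at most one
#' between folds; remainder samples go to the currently smallest folds
#' (ties broken by fold index). Continuous outcomes are stratified by
#' quantile bins (deciles, fewer when n is small) to stabilise regression
#' folds; set `stratify = FALSE` for a plain random partition.
#'
#' @param y Outcome vector (factor/character for classification, numeric
#'   for regression).
#' @param k Number of folds, `2 <= k <= length(y)`.
#' @param seed Integer RNG seed; identical `(y, k, seed)` give identical
#'   folds. The caller's RNG state is left untouched.
#' @param stratify Stratify folds by class (or quantile bin)? Default TRUE.
#' @return List of `k` integer vectors (sorted, disjoint, covering all
#'   indices).
#' @export
make_stratified_folds <- function(y, k, seed = 1L, stratify = TRUE) {
  n <- length(y)
  if (k < 2L) abort_fold_count("k must be at least 2")
  if (k > n) {
    abort_fold_count(sprintf("k (%d) exceeds the number of samples (%d)", k, n))
  }
  if (is.character(y) || is.logical(y)) y <- factor(y)
  classification <- is.factor(y)
  if (classification && nlevels(droplevels(y)) < 2L) {
    abort_degenerate("outcome has a single class; cannot stratify a degenerate outcome")
  }

  strata <- if (!stratify) {
    factor(rep(1L, n))
  } else if (classification) {
    small <- levels(y)[table(y) < k]
    if (length(small)) {
      rlang::warn(paste0("classes with fewer members than folds: ",
                         paste(small, collapse = ", ")))
    }
    droplevels(y)
  } else {
    quantile_bins(y)
  }

  folds <- vector("list", k)
  sizes <- integer(k)
  withr::with_seed(seed, {
    for (cl in levels(strata)) {
      idx <- resample(which(strata == cl))
      m <- length(idx)
      base <- m %/% k
      rem <- m %% k
      pos <- 0L
      if (base > 0L) {
        for (f in seq_len(k)) {
          take <- idx[pos + seq_len(base)]
          folds[[f]] <- c(folds[[f]], take)
          sizes[f] <- sizes[f] + base
          pos <- pos + base
        }
      }
      if (rem > 0L) {
        # leftover samples to the smallest folds, ties by fold index
        target <- order(sizes, seq_len(k))[seq_len(rem)]
        for (j in seq_len(rem)) {
          f <- target[j]
          folds[[f]] <- c(folds[[f]], idx[pos + j])
          sizes[f] <- sizes[f] + 1L
        }
      }
    }
  })
  lapply(folds, function(f) sort(as.integer(f)))
}

quantile_bins <- function(y, max_bins = 10L) {
  n <- length(y)
  n_bins <- max(2L, min(max_bins, n %/% 2L))
  br <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE))
  if (length(br) < 3L) return(factor(rep(1L, n)))
  cut(y, breaks = br, include.lowest = TRUE)
}

#' Plan nested outer/inner cross-validation folds
#'
#' Builds `k_outer` outer test folds and, for each, `l_inner` inner folds
#' partitioning that outer fold's *training* indices only — inner folds
#' never contain their own outer test samples. Per-outer-fold seeds are
#' derived as `seed + fold index` so downstream stochastic steps are
#' invariant to execution order and worker count.
#'
#' @inheritParams make_stratified_folds
#' @param k_outer,l_inner Outer and inner fold counts (default 10 x 10).
#' @return An object of class `fold_plan` with elements `n_samples`,
#'   `k_outer`, `l_inner`, `outer_folds` (list of k index sets),
#'   `inner_plans` (list of k lists of l index sets, original index scale),
#'   `seed`, `stratify`.
#' @export
make_fold_plan <- function(y, k_outer = 10L, l_inner = 10L, seed = 1L,
                           stratify = TRUE) {
  n <- length(y)
  outer <- make_stratified_folds(y, k_outer, seed = seed, stratify = stratify)
  inner <- vector("list", k_outer)
  for (i in seq_len(k_outer)) {
    train <- setdiff(seq_len(n), outer[[i]])
    sets <- make_stratified_folds(y[train], l_inner,
                                  seed = derive_seed(seed, i),
                                  stratify = stratify)
    inner[[i]] <- lapply(sets, function(s) train[s])
  }
  structure(
    list(n_samples = n, k_outer = as.integer(k_outer),
         l_inner = as.integer(l_inner), outer_folds = outer,
         inner_plans = inner, seed = as.integer(seed), stratify = stratify),
    class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d samples, %d outer x %d inner folds, seed %d\n",
              x$n_samples, x$k_outer, x$l_inner, x$seed))
  invisible(x)
}

#' Serialize a fold plan to JSON (and back)
#'
#' Index lists are written 0-based so a run can be replayed from any
#' language; `fold_plan_from_json` restores 1-based indices.
#'
#' @param plan A `fold_plan`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `fold_plan_to_json`: the JSON string (invisibly when written to
#'   a file). `fold_plan_from_json`: a `fold_plan`.
#' @export
fold_plan_to_json <- function(plan, path = NULL) {
  obj <- list(
    n_samples = plan$n_samples, k_outer = plan$k_outer,
    l_inner = plan$l_inner, seed = plan$seed, stratify = plan$stratify,
    outer_folds = lapply(plan$outer_folds, function(f) f - 1L),
    inner_plans = lapply(plan$inner_plans, function(fs)
      lapply(fs, function(f) f - 1L)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname fold_plan_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
fold_plan_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(
    list(n_samples = as.integer(obj$n_samples),
         k_outer = as.integer(obj$k_outer),
         l_inner = as.integer(obj$l_inner),
         outer_folds = lapply(obj$outer_folds,
                              function(f) as.integer(unlist(f)) + 1L),
         inner_plans = lapply(obj$inner_plans, function(fs)
           lapply(fs, function(f) as.integer(unlist(f)) + 1L)),
         seed = as.integer(obj$seed),
         stratify = isTRUE(obj$stratify)),
    class = "fold_plan")
}

# positions of a plan's inner sets inside the outer-training submatrix
inner_positions <- function(plan, i) {
  train <- setdiff(seq_len(plan$n_samples), plan$outer_folds[[i]])
  lapply(plan$inner_plans[[i]], function(s) match(s, train))
}
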