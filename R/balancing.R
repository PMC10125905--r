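#' Specify class rebalancing for outer training folds
#'
#' Rebalancing is only ever applied by the CV engine to outer *training*
#' rows, immediately before feature filtering — balancing the whole
#' dataset would leak held-out samples into the training folds. Methods:
#' random oversampling of the minority class, random undersampling of the
#' majority class, a combination of both (classes meet at the geometric
#' mean of their counts), or SMOTE interpolation.
#'
#' @param method One of `"none"`, `"oversample"`, `"undersample"`,
#'   `"both"`, `"smote"`.
#' @param k_neighbors SMOTE neighbor count (default 5; truncated to
#'   minority size - 1 when necessary).
#' @param target Desired minority:majority ratio in (0, 1]; default 1
#'   (fully balanced).
#' @param seed Optional integer seed; the engine injects a per-fold seed
#'   when this is `NULL`.
#' @return A `balance_spec`.
#' @export
balance_spec <- function(method = c("none", "oversample", "undersample",
                                    "both", "smote"),
                         k_neighbors = 5L, target = 1, seed = NULL) {
  method <- match.arg(method)
  if (k_neighbors < 1L) abort_contract("k_neighbors must be >= 1")
  if (target <= 0 || target > 1) abort_contract("target must be in (0, 1]")
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 target = target, seed = seed),
            class = "balance_spec")
}

check_balance_y <- function(y) {
  if (is.numeric(y) && !is.factor(y)) {
    nf_abort("balancing is refused for regression outcomes: rebalancing can have a deleterious effect on regression",
             "nestfold_balance_regression")
  }
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) abort_degenerate("outcome has a single class")
  if (nlevels(y) > 2L) abort_contract("balancing supports binary outcomes only")
  y
}

minority_majority <- function(y) {
  tab <- table(y)
  # ties: first level is called the minority; all methods leave ties unchanged
  minority <- names(tab)[which.min(tab)]
  list(min_class = minority,
       maj_class = setdiff(names(tab), minority),
       min_idx = which(y == minority),
       maj_idx = which(y != minority))
}

balanced_out <- function(X, y, keep_idx, extra_rows = NULL, extra_y = NULL,
                         synthetic = NULL) {
  Xb <- X[keep_idx, , drop = FALSE]
  yb <- y[keep_idx]
  if (!is.null(extra_rows)) {
    Xb <- rbind(Xb, extra_rows)
    yb <- factor(c(as.character(yb), as.character(extra_y)),
                 levels = levels(y))
    rownames(Xb) <- NULL
  }
  list(X = Xb, y = yb, synthetic = synthetic)
}

#' Random oversampling of the minority class
#'
#' Duplicates minority rows (sampled with replacement, seeded) until the
#' target minority:majority ratio is met. All original rows are retained
#' and the majority class is untouched.
#'
#' @param X Numeric training matrix.
#' @param y Binary outcome for the training rows.
#' @param spec A [balance_spec()].
#' @return List with the rebalanced `X` and `y`.
#' @export
random_oversample <- function(X, y, spec = balance_spec("oversample")) {
  y <- check_balance_y(y)
  mm <- minority_majority(y)
  need <- ceiling(spec$target * length(mm$maj_idx)) - length(mm$min_idx)
  if (need <= 0) return(balanced_out(X, y, seq_along(y)))
  dup <- withr::with_seed(spec$seed %||% 1L,
                          resample(mm$min_idx, need, replace = TRUE))
  balanced_out(X, y, seq_along(y),
               extra_rows = X[dup, , drop = FALSE], extra_y = y[dup])
}

#' Random undersampling of the majority class
#'
#' Subsamples majority rows without replacement (seeded) down to the
#' target ratio; minority rows are untouched and no rows are fabricated.
#'
#' @inheritParams random_oversample
#' @export
random_undersample <- function(X, y, spec = balance_spec("undersample")) {
  y <- check_balance_y(y)
  mm <- minority_majority(y)
  keep_maj <- floor(length(mm$min_idx) / spec$target)
  if (length(mm$maj_idx) <= keep_maj) return(balanced_out(X, y, seq_along(y)))
  kept <- withr::with_seed(spec$seed %||% 1L,
                           resample(mm$maj_idx, keep_maj))
  balanced_out(X, y, sort(c(mm$min_idx, kept)))
}

#' Combined over- and undersampling
#'
#' The majority class is undersampled and the minority oversampled so both
#' meet an intermediate size — the geometric mean of the two class counts,
#' rounded — then the exact target ratio.
#'
#' @inheritParams random_oversample
#' @export
combo_sample <- function(X, y, spec = balance_spec("both")) {
  y <- check_balance_y(y)
  mm <- minority_majority(y)
  n_min <- length(mm$min_idx); n_maj <- length(mm$maj_idx)
  g <- round(sqrt(n_min * n_maj))
  maj_target <- g
  min_target <- round(spec$target * g)
  if (n_min == min_target && n_maj == maj_target) {
    return(balanced_out(X, y, seq_along(y)))
  }
  withr::with_seed(spec$seed %||% 1L, {
    kept_maj <- if (n_maj > maj_target) resample(mm$maj_idx, maj_target) else mm$maj_idx
    dup <- if (min_target > n_min) {
      resample(mm$min_idx, min_target - n_min, replace = TRUE)
    } else integer()
  })
  balanced_out(X, y, sort(c(mm$min_idx, kept_maj)),
               extra_rows = if (length(dup)) X[dup, , drop = FALSE],
               extra_y = if (length(dup)) y[dup])
}

#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic minority row is `x_i + u * (x_nn - x_i)` where `x_i` is
#' a seeded-randomly chosen minority row, `x_nn` one of its `k_neighbors`
#' nearest minority neighbors (Euclidean distance on unscaled features)
#' and `u ~ Uniform(0, 1)`. Synthesis repeats until the target ratio is
#' met; all original rows are retained. Synthetic rows therefore lie, per
#' coordinate, on the segment between a minority point and one of its
#' nearest minority neighbors. With a single minority member SMOTE falls
#' back to random oversampling with a warning.
#'
#' @inheritParams random_oversample
#' @return List with rebalanced `X` and `y`, plus a `synthetic` tibble
#'   recording each synthetic row's seed row, neighbor row (original row
#'   indices) and interpolation draw `u`.
#' @export
smote <- function(X, y, spec = balance_spec("smote")) {
  y <- check_balance_y(y)
  mm <- minority_majority(y)
  n_min <- length(mm$min_idx)
  if (n_min == 1L) {
    rlang::warn("minority class has a single member; falling back to random oversampling")
    return(random_oversample(X, y, spec))
  }
  need <- ceiling(spec$target * length(mm$maj_idx)) - n_min
  if (need <= 0) return(balanced_out(X, y, seq_along(y)))
  k <- min(spec$k_neighbors, n_min - 1L)
  Xmin <- X[mm$min_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(Xmin))
  nn <- lapply(seq_len(n_min), function(i) {
    others <- setdiff(seq_len(n_min), i)
    others[order(D[i, others], others)][seq_len(k)]
  })
  synth <- matrix(NA_real_, need, ncol(X))
  prov <- matrix(NA_integer_, need, 2L)
  us <- numeric(need)
  withr::with_seed(spec$seed %||% 1L, {
    for (s in seq_len(need)) {
      i <- sample.int(n_min, 1L)
      j <- nn[[i]][sample.int(k, 1L)]
      u <- stats::runif(1)
      synth[s, ] <- Xmin[i, ] + u * (Xmin[j, ] - Xmin[i, ])
      prov[s, ] <- c(mm$min_idx[i], mm$min_idx[j])
      us[s] <- u
    }
  })
  colnames(synth) <- colnames(X)
  balanced_out(X, y, seq_along(y), extra_rows = synth,
               extra_y = rep(mm$min_class, need),
               synthetic = tibble::tibble(seed_row = prov[, 1L],
                                          neighbor_row = prov[, 2L],
                                          u = us))
}

# engine-facing dispatcher; returns X, y, and a pre/post count summary
apply_balance <- function(X, y, spec, seed = NULL) {
  if (is.null(spec) || spec$method == "none") {
    out <- list(X = X, y = y, synthetic = NULL)
  } else {
    if (!is.null(seed) && is.null(spec$seed)) spec$seed <- seed
    out <- switch(spec$method,
                  oversample = random_oversample(X, y, spec),
                  undersample = random_undersample(X, y, spec),
                  both = combo_sample(X, y, spec),
                  smote = smote(X, y, spec))
  }
  out$summary <- if (is.factor(y)) {
    tibble::tibble(class = levels(y),
                   n_before = as.integer(table(factor(y, levels(y)))),
                   n_after = as.integer(table(factor(out$y, levels(y)))))
  }
  out
}
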