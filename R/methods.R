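#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the pooled out-of-fold predictions of a nested-CV run
#'
#' @param x A `nestcv_result`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `fold`, `truth`, `score`.
#' @export
tidy.nestcv_result <- function(x, ...) x$pooled

#' One-row performance summary of a nested-CV run
#'
#' @param x A `nestcv_result`.
#' @param ... Unused.
#' @return One-row tibble of pooled metrics, plus `inner_auc` (the biased
#'   inner-CV estimate) when available.
#' @export
glance.nestcv_result <- function(x, ...) {
  out <- x$metrics
  if (!is.null(x$inner_cv_metrics) && "auc" %in% names(x$inner_cv_metrics)) {
    out$inner_auc <- x$inner_cv_metrics$auc
  }
  out
}

#' Per-fold tuning and performance table
#'
#' @param x A `nestcv_result`.
#' @param ... Unused.
#' @return Tibble with one row per outer fold: `fold`, `n_selected`,
#'   `alpha`, `lambda`, `fold_metric`.
#' @export
augment.nestcv_result <- function(x, ...) fold_table(x)

#' @importFrom generics augment
#' @export
generics::augment

#' @export
tidy.filter_result <- function(x, ...) x$kept

#' @export
tidy.tuned_learner <- function(x, ...) {
  x$score_table %||% tibble::tibble(alpha = x$params$alpha %||% NA_real_,
                                    lambda = x$params$lambda %||% NA_real_,
                                    score = x$score)
}

#' @export
glance.tuned_learner <- function(x, ...) {
  tibble::tibble(learner = x$learner,
                 alpha = x$params$alpha %||% NA_real_,
                 lambda = x$params$lambda %||% NA_real_,
                 metric = x$metric, score = x$score)
}

#' @export
tidy.bias_experiment <- function(x, ...) x$results

#' @export
glance.bias_experiment <- function(x, ...) {
  summarize_bias(x) |>
    tidyr_pivot_wider_bias()
}

# one row, columns <scheme>_mean / <scheme>_sd (no tidyr dependency needed)
tidyr_pivot_wider_bias <- function(summ) {
  out <- tibble::tibble(.rows = 1L)
  for (i in seq_len(nrow(summ))) {
    out[[paste0(summ$scheme[i], "_mean")]] <- summ$mean_auc[i]
    out[[paste0(summ$scheme[i], "_sd")]] <- summ$sd_auc[i]
  }
  out
}
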