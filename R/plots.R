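#' Plot an ROC curve
#'
#' @param object An `nf_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nf_roc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)",
                                  attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot the pooled out-of-fold ROC curve of a nested-CV run
#'
#' @param object A `nestcv_result` (classification).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nestcv_result <- function(object, ...) {
  if (is.null(object$roc)) {
    abort_contract("no ROC curve: this is a regression result")
  }
  autoplot(object$roc) +
    ggplot2::labs(subtitle = "Pooled out-of-fold predictions (unbiased)")
}

#' Plot the bias experiment: AUC by estimation scheme
#'
#' Boxplots of per-repeat AUCs for each scheme, with the chance line at
#' 0.5. On pure-noise data only the whole-data-filter scheme sits above
#' chance.
#'
#' @param object A `bias_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bias_experiment <- function(object, ...) {
  df <- object$results
  df$scheme <- factor(df$scheme,
                      levels = c("filter_then_partition",
                                 "partition_then_filter", "nested_cv"),
                      labels = c("Filter then\npartition",
                                 "Partition then\nfilter", "Nested CV"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme, y = .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "ROC AUC",
                  title = "Selection bias on pure-noise data") +
    ggplot2::theme_minimal()
}

#' Plot final-model variable importance
#'
#' @param result A `nestcv_result` with a final model.
#' @param top_n Show at most this many predictors (default 25).
#' @return A ggplot.
#' @export
plot_importance <- function(result, top_n = 25L) {
  if (is.null(result$final)) abort_contract("result has no final model")
  imp <- utils::head(variable_importance(result$final$model), top_n)
  imp$predictor <- stats::reorder(imp$predictor, imp$importance)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance,
                                    y = .data$predictor)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Importance", y = NULL,
                  title = "Final model variable importance") +
    ggplot2::theme_minimal()
}
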