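#' ROC area under the curve by pair counting
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)`,
#' computed via the Mann-Whitney rank identity (midranks give tied pairs
#' half credit, so the value is exact under ties).
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Binary labels: a two-level factor (second level =
#'   positive), logical, or 0/1 numeric.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    nf_abort("AUC is undefined with a single class", "nestfold_undefined_metric")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) {
      abort_contract("numeric labels must be 0/1")
    }
    return(labels == 1)
  }
  labels <- factor(labels)
  if (nlevels(labels) > 2L) abort_contract("labels must be binary")
  labels == levels(labels)[2L]
}

#' ROC curve at every distinct score
#'
#' Operating points follow the rule "score >= threshold is positive", with
#' thresholds at `+Inf` and every distinct score, so the curve runs from
#' (sensitivity 0, specificity 1) to (sensitivity 1, specificity 0). Its
#' trapezoidal area equals the pair-counting AUC.
#'
#' @inheritParams roc_auc
#' @return A tibble of class `nf_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, and an `auc` attribute (trapezoidal
#'   area).
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    nf_abort("ROC curve is undefined with a single class",
             "nestfold_undefined_metric")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & pos) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !pos) / n0, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  out <- tibble::tibble(threshold = thr, sensitivity = sens,
                        specificity = spec)
  class(out) <- c("nf_roc", class(out))
  attr(out, "auc") <- auc
  out
}

#' Classification performance summary from pooled predictions
#'
#' Hard calls use the rule "score >= threshold is positive" (the tie rule
#' matters for accuracy at 0.5). Balanced accuracy is the mean of the two
#' per-class recalls, robust to class imbalance.
#'
#' @inheritParams roc_auc
#' @param threshold Probability cutoff for hard calls (default 0.5).
#' @return One-row tibble with `auc`, `accuracy`, `balanced_accuracy`.
#' @export
classification_summary <- function(scores, labels, threshold = 0.5) {
  pos <- as_positive(labels)
  call_pos <- scores >= threshold
  sens <- sum(call_pos & pos) / sum(pos)
  spec <- sum(!call_pos & !pos) / sum(!pos)
  tibble::tibble(
    auc = roc_auc(scores, labels),
    accuracy = mean(call_pos == pos),
    balanced_accuracy = (sens + spec) / 2)
}

#' Regression performance summary from pooled predictions
#'
#' @param predictions Predicted values.
#' @param truth Observed values.
#' @return One-row tibble with `rmse` and `r_squared`
#'   (`1 - SS_res / SS_tot`).
#' @export
regression_summary <- function(predictions, truth) {
  ss_res <- sum((predictions - truth)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  tibble::tibble(
    rmse = sqrt(mean((predictions - truth)^2)),
    r_squared = 1 - ss_res / ss_tot)
}

#' Write an ROC curve as TSV (threshold, sensitivity, specificity)
#' @param roc An `nf_roc`.
#' @param path Output file path.
#' @export
write_roc_tsv <- function(roc, path) {
  readr::write_tsv(tibble::as_tibble(roc), path)
  invisible(path)
}
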