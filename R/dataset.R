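#' Construct a modelling dataset from a feature matrix and outcome
#'
#' A dataset couples an `n x P` numeric feature matrix with an outcome
#' vector, sample identifiers and predictor names. Classification outcomes
#' (factor, character or logical) are stored as factors with sorted levels;
#' the *second* level is the positive class throughout the package.
#' Numeric outcomes are treated as regression targets.
#'
#' @param X Numeric matrix, samples in rows, predictors in columns.
#' @param y Outcome vector of length `nrow(X)`.
#' @param sample_ids Optional unique sample identifiers (default: rownames
#'   of `X`, else `"S1"..."Sn"`).
#' @param predictor_names Optional unique predictor names (default:
#'   colnames of `X`, else `"V1"..."VP"`).
#' @param allow_missing Permit `NA` feature values (they must then be
#'   handled downstream, e.g. by the engine's training-fold median
#'   imputation). Default `FALSE`: missing values are an error.
#' @return An object of class `nf_dataset`.
#' @export
new_dataset <- function(X, y, sample_ids = NULL, predictor_names = NULL,
                        allow_missing = FALSE) {
  X <- as.matrix(X)
  if (!is.numeric(X)) abort_contract("feature matrix must be numeric")
  n <- nrow(X)
  if (length(y) != n) {
    abort_contract(sprintf("outcome length (%d) != number of rows (%d)",
                           length(y), n))
  }
  if (!allow_missing && anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    abort_contract(sprintf(
      "missing feature value at row %d, column %d; impute upstream or set allow_missing = TRUE",
      bad[1L], bad[2L]))
  }
  if (anyNA(y)) abort_contract("missing values in outcome are not supported")

  sample_ids <- sample_ids %||% rownames(X) %||% paste0("S", seq_len(n))
  predictor_names <- predictor_names %||% colnames(X) %||%
    paste0("V", seq_len(ncol(X)))
  if (anyDuplicated(sample_ids)) abort_contract("duplicate sample ids")
  if (anyDuplicated(predictor_names)) abort_contract("duplicate predictor names")
  dimnames(X) <- list(sample_ids, predictor_names)

  if (is.character(y) || is.logical(y)) y <- factor(y)
  if (is.factor(y)) {
    y <- factor(as.character(y))  # sorted levels; drop unused
    outcome_type <- if (nlevels(y) == 2L) "binomial" else "multiclass"
  } else {
    outcome_type <- "gaussian"
  }

  structure(
    list(X = X, y = y, sample_ids = as.character(sample_ids),
         predictor_names = as.character(predictor_names),
         outcome_type = outcome_type),
    class = "nf_dataset")
}

#' Build a dataset from a data frame with an outcome column
#'
#' Tidy entry point: all non-outcome columns become the feature matrix.
#'
#' @param data A data frame (or tibble), samples in rows.
#' @param outcome Name of the outcome column.
#' @param sample_ids Optional column name holding sample identifiers; that
#'   column is removed from the features.
#' @inheritParams new_dataset
#' @return An `nf_dataset`.
#' @export
as_dataset <- function(data, outcome, sample_ids = NULL,
                       allow_missing = FALSE) {
  if (inherits(data, "nf_dataset")) return(data)
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    abort_contract(sprintf("outcome column '%s' not found", outcome))
  }
  y <- data[[outcome]]
  ids <- NULL
  drop <- outcome
  if (!is.null(sample_ids)) {
    if (!sample_ids %in% names(data)) {
      abort_contract(sprintf("sample id column '%s' not found", sample_ids))
    }
    ids <- as.character(data[[sample_ids]])
    drop <- c(drop, sample_ids)
  }
  feats <- data[setdiff(names(data), drop)]
  not_num <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(not_num)) {
    abort_contract(paste0("non-numeric feature columns: ",
                          paste(utils::head(not_num, 5), collapse = ", ")))
  }
  new_dataset(as.matrix(feats), y, sample_ids = ids,
              allow_missing = allow_missing)
}

#' @export
print.nf_dataset <- function(x, ...) {
  cat(sprintf("<nf_dataset> %d samples x %d predictors, outcome: %s\n",
              nrow(x$X), ncol(x$X), x$outcome_type))
  if (is.factor(x$y)) {
    tab <- table(x$y)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        sprintf("(positive class: %s)\n", levels(x$y)[2L]))
  }
  invisible(x)
}

#' @export
dim.nf_dataset <- function(x) dim(x$X)

# positive class convention: second level of the sorted label set
positive_class <- function(y) levels(y)[2L]
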