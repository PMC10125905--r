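#' Read a delimited feature table into a dataset
#'
#' Reads a CSV/TSV file with a header. With `orientation =
#' "samples_in_rows"` (default) each row is a sample and `outcome` names a
#' column. With `orientation = "predictors_in_rows"` (the transcriptomics
#' convention) the first column holds predictor names, the remaining
#' column names are sample ids, and the table is transposed; `outcome`
#' then names a *row* of the original table. Non-numeric feature cells,
#' duplicate names and (by default) missing values are rejected with an
#' explicit error.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file (delimiter inferred
#'   from the extension).
#' @param outcome Name of the outcome column (or row, when predictors are
#'   in rows).
#' @param orientation `"samples_in_rows"` or `"predictors_in_rows"`.
#' @param id_column Optional sample-id column name
#'   (samples-in-rows only; default: first column when it is non-numeric
#'   character and unique, else row numbers).
#' @param allow_missing Permit `NA` feature values for downstream
#'   training-fold imputation (default FALSE).
#' @return An [nf_dataset][new_dataset()].
#' @export
read_dataset <- function(path, outcome,
                         orientation = c("samples_in_rows",
                                         "predictors_in_rows"),
                         id_column = NULL, allow_missing = FALSE) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (orientation == "predictors_in_rows") {
    pred_names <- as.character(tab[[1L]])
    if (anyDuplicated(pred_names)) abort_contract("duplicate predictor names")
    m <- t(as.matrix(tab[-1L]))
    colnames(m) <- pred_names
    df <- as.data.frame(m)
    df[["..sample_id"]] <- rownames(m)
    if (!outcome %in% pred_names) {
      abort_contract(sprintf("outcome row '%s' not found", outcome))
    }
    y_raw <- df[[outcome]]
    df[[outcome]] <- NULL
    # the outcome row forces every transposed column to character;
    # convert features back, flagging genuinely non-numeric cells
    feat_cols <- setdiff(names(df), "..sample_id")
    for (nm in feat_cols) {
      col <- df[[nm]]
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad)) {
        abort_contract(sprintf(
          "non-numeric feature cell at sample %d, predictor '%s'", bad[1L], nm))
      }
      df[[nm]] <- num
    }
    check_numeric_cells(df[feat_cols], allow_missing)
    df[[outcome]] <- parse_outcome(y_raw)
    return(as_dataset(df, outcome, sample_ids = "..sample_id",
                      allow_missing = allow_missing))
  }
  if (!outcome %in% names(tab)) {
    abort_contract(sprintf("outcome column '%s' not found", outcome))
  }
  if (is.null(id_column)) {
    first <- names(tab)[1L]
    if (first != outcome && is.character(tab[[first]]) &&
        !anyDuplicated(tab[[first]])) {
      id_column <- first
    }
  }
  feats <- tab[setdiff(names(tab), c(outcome, id_column))]
  check_numeric_cells(feats, allow_missing)
  as_dataset(as.data.frame(tab), outcome, sample_ids = id_column,
             allow_missing = allow_missing)
}

check_numeric_cells <- function(feats, allow_missing) {
  for (nm in names(feats)) {
    col <- feats[[nm]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      abort_contract(sprintf("non-numeric feature cell at row %d, column '%s'",
                             bad %||% 1L, nm))
    }
    if (!allow_missing && anyNA(col)) {
      abort_contract(sprintf("missing value at row %d, column '%s'",
                             which(is.na(col))[1L], nm))
    }
  }
  invisible(TRUE)
}

parse_outcome <- function(y) {
  num <- suppressWarnings(as.numeric(y))
  if (!anyNA(num)) num else factor(as.character(y))
}

#' Write a dataset back to delimited text (samples in rows)
#'
#' @param dataset An `nf_dataset`.
#' @param path Output path (`.csv` or `.tsv`).
#' @param outcome Name for the outcome column (default `"outcome"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, outcome = "outcome") {
  df <- tibble::as_tibble(dataset$X)
  df <- tibble::add_column(df, sample_id = dataset$sample_ids,
                           .before = 1L)
  df[[outcome]] <- dataset$y
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}
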