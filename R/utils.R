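# internal helpers: classed errors so callers can distinguish contract failures

nf_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "nestfold_error"), ...)
}

abort_fold_count <- function(msg) nf_abort(msg, "nestfold_fold_count_error")
abort_degenerate <- function(msg) nf_abort(msg, "nestfold_degenerate_outcome")
abort_contract <- function(msg) nf_abort(msg, "nestfold_contract_violation")

# seeds derived from a base seed must stay valid 32-bit integers
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) + as.double(offset)) %% 2147483647
  as.integer(s)
}

is_binary <- function(y) is.factor(y) && nlevels(y) == 2L

# column variances without forming a full centred copy per group more than once
col_vars <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(NA_real_, ncol(X)))
  m <- colMeans(X)
  colSums((X - rep(m, each = n))^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() misbehaves on length-1 vectors; always index positions
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
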