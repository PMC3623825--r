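# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
NULL

# Coerce a samples-by-variables table to a plain numeric matrix with column
# names. Data frames (tibbles included) and matrices are accepted everywhere a
# dataset is expected.
as_data_matrix <- function(data, arg = "data") {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort(sprintf("`%s` must be a numeric matrix or data frame.", arg))
  }
  if (anyNA(data)) abort(sprintf("`%s` must not contain missing values.", arg))
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))
  if (nrow(data) < 2L) abort(sprintf("`%s` needs at least 2 rows (samples).", arg))
  data
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic K-fold assignment: a seeded shuffle of balanced fold labels.
cv_fold_assignment <- function(n, folds, seed) {
  stopifnot(folds >= 2L, n >= folds)
  with_seed_(seed, sample(rep_len(seq_len(folds), n)))
}

check_scalar_number <- function(x, arg, lower = -Inf, upper = Inf,
                                strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s.",
      arg, if (strict) "(" else "[", format(lower), format(upper),
      if (strict) ")" else "]"
    ))
  }
  invisible(x)
}

upper_pairs <- function(p) {
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
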