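#' Construct a labelled distance matrix
#'
#' Distance matrices throughout the package are plain numeric matrices with
#' identical row and column labels, a zero diagonal, symmetry and finite
#' nonnegative entries. This constructor validates those invariants.
#'
#' @param m numeric square matrix.
#' @param labels optional character vector of labels; defaults to the
#'   dimnames of `m`.
#' @return the validated matrix with dimnames set to `labels`.
#' @export
distance_matrix <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  if (is.null(labels)) stopf("distance matrix needs labels")
  if (nrow(m) != ncol(m)) stopf("distance matrix must be square")
  if (length(labels) != nrow(m)) stopf("label length does not match matrix")
  if (anyDuplicated(labels)) stopf("duplicate labels in distance matrix")
  dimnames(m) <- list(labels, labels)
  validate_distance_matrix(m)
  m
}

validate_distance_matrix <- function(m) {
  if (!all(is.finite(m))) stopf("distance matrix has non-finite entries")
  if (any(m < 0)) stopf("distance matrix has negative entries")
  if (any(abs(diag(m)) > 1e-12)) stopf("distance matrix diagonal is not zero")
  if (max(abs(m - t(m))) > 1e-9) stopf("distance matrix is not symmetric")
  invisible(m)
}

#' Standardize a distance matrix to the unit interval
#'
#' Divides every entry by the maximum off-diagonal entry, so the result lies
#' in \[0, 1\] with the largest distance equal to 1. Division by the maximum
#' (rather than min-max rescaling) preserves zero self-distances and all
#' distance ratios; the operation is idempotent and invariant to a positive
#' rescaling of the input.
#'
#' @param m a distance matrix (see [distance_matrix()]).
#' @return the rescaled matrix.
#' @export
standardize_unit <- function(m) {
  validate_distance_matrix(m)
  mx <- max(m[upper.tri(m)])
  if (mx <= 0) stopf("degenerate distances: all off-diagonal entries are zero")
  m / mx
}

## Strictly-lower-triangle vector in a fixed (column-major) order.
lower_vec <- function(m) m[lower.tri(m)]
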