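## Blending functional and phylogenetic distances, and their concordance.

#' Functional-phylogenetic distance (FPDist)
#'
#' Entrywise blend of a phylogenetic and a functional distance matrix:
#' FPDist_ij = (alpha * PDist_ij^rho + (1 - alpha) * FDist_ij^rho)^(1/rho).
#' With alpha = 0 the result equals the functional matrix, with alpha = 1
#' the phylogenetic matrix; rho (an integer >= 1) controls the
#' nonlinearity of the blend, and rho = 1 gives the arithmetic mixture.
#'
#' @param pd,fd distance matrices with identical labels in identical order,
#'   both with entries in \[0, 1\].
#' @param alpha weighting parameter in \[0, 1\]; the contribution of the
#'   phylogenetic matrix.
#' @param rho integer >= 1 (the study default is 2).
#' @return a distance matrix with entries in \[0, 1\].
#' @export
fp_distance <- function(pd, fd, alpha, rho = 2L) {
  if (!identical(rownames(pd), rownames(fd))) {
    stopf("label mismatch between PDist and FDist")
  }
  stopifnot(alpha >= 0, alpha <= 1, rho >= 1, rho == as.integer(rho))
  if (max(pd) > 1 + 1e-9 || max(fd) > 1 + 1e-9) {
    stopf("fp_distance expects matrices standardized to [0, 1]")
  }
  if (alpha == 0) return(fd)
  if (alpha == 1) return(pd)
  m <- (alpha * pd^rho + (1 - alpha) * fd^rho)^(1 / rho)
  diag(m) <- 0
  distance_matrix(m)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle distance vectors,
#' with significance from simultaneous row/column permutations of the
#' second matrix (via [vegan::mantel()]). The one-tailed "greater"
#' alternative tests for concordance; p = (#\{null r >= observed\} + 1) /
#' (n_perm + 1).
#'
#' @param d1,d2 distance matrices over the same labels.
#' @param n_perm number of permutations (study default 9999).
#' @param seed integer RNG seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1) {
  if (!setequal(rownames(d1), rownames(d2))) stopf("label sets differ")
  d2 <- d2[rownames(d1), rownames(d1)]
  stopifnot(n_perm >= 1)
  if (stats::sd(lower_vec(d1)) == 0 || stats::sd(lower_vec(d2)) == 0) {
    stopf("constant off-diagonal distances: Mantel r undefined")
  }
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
    method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), p = unname(fit$signif), n_perm = n_perm)
}
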