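## Phylogenetic distances: K2P pairwise divergence, neighbour-joining tree,
## bootstrap support, patristic distances, and the unit-standardized PDist.

## integer coding A=1 C=2 G=3 T=4; anything else (N, gaps) 0 and excluded
## pairwise from each comparison.
seq_codes <- function(aln) {
  m <- do.call(rbind, lapply(strsplit(unclass(aln), ""), function(v) {
    i <- match(v, c("A", "C", "G", "T"))
    i[is.na(i)] <- 0L
    i
  }))
  rownames(m) <- names(aln)
  m
}

count_pair_codes <- function(a, b) {
  ok <- a > 0L & b > 0L
  n <- sum(ok)
  if (n == 0) stopf("no overlap: zero comparable sites")
  a <- a[ok]; b <- b[ok]
  dif <- a != b
  pur_a <- a == 1L | a == 3L
  pur_b <- b == 1L | b == 3L
  ts <- sum(dif & pur_a == pur_b)   # A<->G, C<->T
  c(n_compared = n, n_transitions = ts, n_transversions = sum(dif) - ts)
}

#' Count comparable, transition and transversion sites for a sequence pair
#'
#' Sites where either sequence carries a symbol other than A/C/G/T (gaps,
#' N) are excluded pairwise. Transitions are A<->G and C<->T; every other
#' mismatch is a transversion.
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @return named integer vector `n_compared`, `n_transitions`,
#'   `n_transversions`.
#' @export
count_site_pairs <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stopf("sequences differ in length")
  code <- function(s) {
    i <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
    i[is.na(i)] <- 0L
    i
  }
  count_pair_codes(code(seq_a), code(seq_b))
}

#' Kimura two-parameter distance from site-pair counts
#'
#' With transition proportion P and transversion proportion Q over the
#' compared sites, the K2P divergence is
#' d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q)) substitutions per site.
#'
#' @param counts vector as returned by [count_site_pairs()].
#' @return nonnegative divergence; errors with a "saturation" message when
#'   the logarithm's argument is not positive.
#' @export
k2p_distance <- function(counts) {
  n <- counts[["n_compared"]]
  if (n <= 0) stopf("no overlap: zero comparable sites")
  P <- counts[["n_transitions"]] / n
  Q <- counts[["n_transversions"]] / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stopf("saturation: K2P distance undefined (P = %.4f, Q = %.4f)", P, Q)
  }
  -0.5 * log(w1 * sqrt(w2))
}

k2p_matrix_codes <- function(codes) {
  n <- nrow(codes)
  labs <- rownames(codes)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch(k2p_distance(count_pair_codes(codes[i, ], codes[j, ])),
        error = function(e) {
          stopf("pair (%s, %s): %s", labs[i], labs[j], conditionMessage(e))
        })
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' Pairwise K2P distance matrix from an alignment
#'
#' @param aln an `aligned_sequences` object.
#' @return a distance matrix in substitutions/site; any saturated or
#'   non-overlapping pair aborts with the pair named.
#' @export
k2p_matrix <- function(aln) {
  if (length(aln) < 2) stopf("need at least 2 sequences")
  distance_matrix(k2p_matrix_codes(seq_codes(aln)))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]). Negative branch
#' lengths, which NJ can produce on non-additive inputs, are clamped to
#' zero with the deficit transferred to the sibling branch so path lengths
#' are approximately preserved; each clamp is reported via a message.
#'
#' @param dm a distance matrix with at least 3 labels.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  validate_distance_matrix(dm)
  if (nrow(dm) < 3) stopf("neighbour-joining needs at least 3 labels")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)[1]
    if (!is.na(sib)) tr$edge.length[sib] <- tr$edge.length[sib] + deficit
    tr$edge.length[e] <- 0
    message(sprintf("nj_tree: clamped negative branch (%.3g) at edge %d", deficit, e))
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the NJ tree
#'
#' Alignment columns are resampled with replacement; each replicate is run
#' through [k2p_matrix()] and [nj_tree()], and the support of each internal
#' edge of the original tree is the fraction of successful replicates whose
#' tree contains that bipartition. Replicates whose K2P computation fails
#' (saturation or no overlap) are skipped and reported.
#'
#' @param aln an `aligned_sequences` object.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return the original NJ tree with `node.label` set to supports in \[0, 1\].
#' @export
bootstrap_support <- function(aln, n_reps, seed) {
  stopifnot(n_reps >= 1)
  codes <- seq_codes(aln)
  ref <- nj_tree(distance_matrix(k2p_matrix_codes(codes)))
  set.seed(seed)
  boots <- vector("list", n_reps)
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(codes), ncol(codes), replace = TRUE)
    boots[[r]] <- tryCatch(
      suppressMessages(nj_tree(distance_matrix(k2p_matrix_codes(codes[, cols, drop = FALSE])))),
      error = function(e) NULL)
    if (is.null(boots[[r]])) n_fail <- n_fail + 1L
  }
  boots <- Filter(Negate(is.null), boots)
  if (length(boots) == 0) stopf("all %d bootstrap replicates failed", n_reps)
  if (n_fail > 0) {
    message(sprintf("bootstrap_support: %d of %d replicates failed and were skipped",
      n_fail, n_reps))
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / length(boots)
  ref
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the path between leaves
#' i and j.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return a distance matrix over the tip labels.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  m <- stats::cophenetic(tree)
  m <- (m + t(m)) / 2
  distance_matrix(m)
}

#' Unit-standardized phylogenetic distance matrix (PDist)
#'
#' The default route builds the NJ tree from the K2P matrix and
#' standardizes its patristic distances to \[0, 1\], so PDist reflects the
#' tree's branch lengths. The "direct" route standardizes the K2P matrix
#' itself without tree mediation.
#'
#' @param aln an `aligned_sequences` object.
#' @param route `"tree"` (default) or `"direct"`.
#' @return a distance matrix with entries in \[0, 1\] (max off-diagonal 1).
#' @export
pdist_matrix <- function(aln, route = c("tree", "direct")) {
  route <- match.arg(route)
  k2p <- k2p_matrix(aln)
  if (route == "direct" || nrow(k2p) < 3) {
    return(standardize_unit(k2p))
  }
  m <- patristic_matrix(nj_tree(k2p))
  standardize_unit(m[rownames(k2p), rownames(k2p)])
}
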