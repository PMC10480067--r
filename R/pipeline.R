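#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the study defaults:
#' blend exponent rho = 2, a 41-level alpha grid from 0 to 1 in steps of
#' 0.025, 999 null-model randomizations, 999 bootstrap resamples for the
#' effect-size confidence intervals, 9999 Mantel permutations and 3000
#' tree-bootstrap replicates.
#'
#' @param seed master RNG seed; every stochastic stage derives a named
#'   sub-seed from it.
#' @param rho integer blend exponent (>= 1).
#' @param alpha_grid sorted vector of blend weights in \[0, 1\].
#' @param n_null null-model randomizations per sample.
#' @param n_boot bootstrap resamples for CI of the mean effect size.
#' @param n_mantel Mantel permutations (0 skips the Mantel test).
#' @param n_tree_boot tree-bootstrap replicates (0 skips bootstrap support).
#' @param pdist_route `"tree"` (standardized NJ patristic distances, the
#'   default) or `"direct"` (standardized K2P matrix).
#' @param position scale of the sampling position in the linear model:
#'   `"distance_m"` (metres, default) or `"rank"` (ordinal site rank).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, rho = 2L,
                            alpha_grid = seq(0, 1, by = 0.025),
                            n_null = 999, n_boot = 999, n_mantel = 9999,
                            n_tree_boot = 3000,
                            pdist_route = c("tree", "direct"),
                            position = c("distance_m", "rank")) {
  stopifnot(rho >= 1, rho == as.integer(rho),
    all(alpha_grid >= 0), all(alpha_grid <= 1), !is.unsorted(alpha_grid),
    n_null >= 1, n_boot >= 1, n_mantel >= 0, n_tree_boot >= 0)
  structure(list(
    seed = as.integer(seed), rho = as.integer(rho), alpha_grid = alpha_grid,
    n_null = n_null, n_boot = n_boot, n_mantel = n_mantel,
    n_tree_boot = n_tree_boot, pdist_route = match.arg(pdist_route),
    position = match.arg(position)
  ), class = "pipeline_config")
}

#' Run the full functional-phylogenetic assembly analysis
#'
#' Orchestrates the whole chain: Gower functional distances (FDist), K2P +
#' neighbour-joining phylogenetic distances standardized to \[0, 1\]
#' (PDist), a Mantel concordance test, per-sample abundance-weighted MPD
#' effect sizes against richness-constrained nulls across the alpha grid,
#' per-season selection of the optimal blend weight, per-site mean effect
#' sizes with bootstrap CIs, and Rao's quadratic entropy at the optimal
#' alpha. All matrices are computed over the regional species pool (the
#' union of species observed in the community matrix). Deterministic given
#' the config seed.
#'
#' @param traits a `trait_table` covering every community species.
#' @param alignment an `aligned_sequences` covering every community species.
#' @param communities a `community_matrix`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, tidy CSV result tables,
#'   the Newick tree and the serialized configuration are written there.
#' @return an `fpdiv_pipeline` list: `fdist`, `k2p`, `tree` (NJ tree, with
#'   bootstrap node supports when `n_tree_boot > 0`), `pdist`, `mantel`,
#'   and the [alpha_sweep()] tables (`sweep`, `optimal`, `es`,
#'   `site_summary`, `rao`).
#' @export
run_pipeline <- function(traits, alignment, communities,
                         config = pipeline_config(), out_dir = NULL) {
  pool <- sort(comm_species(communities))
  miss_t <- setdiff(pool, traits$species)
  if (length(miss_t)) stopf("species missing from trait table: %s", toString(miss_t))
  miss_a <- setdiff(pool, names(alignment))
  if (length(miss_a)) stopf("species missing from alignment: %s", toString(miss_a))

  traits <- trait_table(as.data.frame(traits)[match(pool, traits$species), ])
  aln <- aligned_sequences(unclass(alignment)[pool])

  fd <- gower_matrix(traits)[pool, pool]
  k2p <- k2p_matrix(aln)
  tree <- if (config$n_tree_boot > 0) {
    bootstrap_support(aln, config$n_tree_boot, sub_seed(config$seed, "treeboot"))
  } else {
    nj_tree(k2p)
  }
  pd <- if (config$pdist_route == "direct") {
    standardize_unit(k2p)
  } else {
    standardize_unit(patristic_matrix(tree))[pool, pool]
  }

  mantel <- if (config$n_mantel > 0) {
    mantel_test(fd, pd, config$n_mantel, sub_seed(config$seed, "mantel"))
  } else NULL

  sweep <- alpha_sweep(pd, fd, communities, config)

  res <- structure(c(
    list(fdist = fd, k2p = k2p, tree = tree, pdist = pd, mantel = mantel,
      config = config),
    unclass(sweep)
  ), class = "fpdiv_pipeline")

  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @rdname run_pipeline
#' @param res an `fpdiv_pipeline` result.
#' @export
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(res$sweep, "alpha_sweep.csv")
  wcsv(res$optimal, "optimal_alpha.csv")
  wcsv(res$es, "sample_es.csv")
  wcsv(res$site_summary, "site_mean_es.csv")
  wcsv(res$rao, "rao_q.csv")
  if (!is.null(res$mantel)) {
    wcsv(data.frame(r = res$mantel$r, p = res$mantel$p,
      n_perm = res$mantel$n_perm), "mantel.csv")
  }
  ape::write.tree(res$tree, file.path(out_dir, "nj_tree.nwk"))
  cfg <- unclass(res$config)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.fpdiv_pipeline <- function(x, ...) {
  cat("Functional-phylogenetic assembly analysis\n")
  cat(sprintf("  species pool: %d, samples: %d\n",
    nrow(x$fdist), nrow(x$es %||% data.frame())))
  if (!is.null(x$mantel)) {
    cat(sprintf("  Mantel FDist~PDist: r = %.4f, p = %.4g (%d permutations)\n",
      x$mantel$r, x$mantel$p, x$mantel$n_perm))
  }
  if (!is.null(x$optimal)) {
    for (i in seq_len(nrow(x$optimal))) {
      cat(sprintf("  %s: optimal alpha = %s (adj R^2 = %.3f)\n",
        x$optimal$season[i], format(x$optimal$alpha_optimal[i]),
        x$optimal$adj_r2[i]))
    }
  }
  invisible(x)
}
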