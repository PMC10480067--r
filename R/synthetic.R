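## Synthetic study generator: a Yule tree, K2P sequences, conserved traits
## and communities assembled under known rules along a distance gradient.
## Defaults mirror the study design: a ~24-species regional pool, five
## sites at 0/500/2500/3000/3500 m from an effluent inflow, and three
## sampling dates in each of three seasons.

STUDY_DATES <- list(
  spring = c("2016-04-20", "2016-05-10", "2016-06-01"),
  summer = c("2016-06-29", "2016-07-21", "2016-08-10"),
  autumn = c("2016-08-30", "2016-09-21", "2016-10-24")
)

#' Scenario specification for community assembly
#'
#' @param scenario `"neutral"`, `"filtering"` (environmental filtering whose
#'   strength decays with distance from the inflow) or `"limiting"`
#'   (limiting similarity: residents repel too-similar candidates).
#' @param n_species regional pool size.
#' @param distances_m site distances from the effluent inflow, strictly
#'   increasing; sites are labelled K1, K2, ...
#' @param n_dates_per_season sampling dates per season.
#' @param filter_strength filtering intensity at 0 m (decays linearly to 0
#'   at the farthest site).
#' @param axis trait axis the assembly rule acts on: `"functional"` (first
#'   principal coordinate of the Gower matrix) or `"phylogenetic"` (first
#'   principal coordinate of PDist).
#' @param min_dist limiting-similarity threshold: candidates within this
#'   distance (in the chosen matrix) of a resident are rejected.
#' @param richness_range integer range samples' species richness is drawn
#'   from; defaults to 5-15 species, except 3-4 under `"limiting"`: with
#'   conserved traits the pool holds near-duplicate phenotypes, so only a
#'   handful of mutually distant species exist at any useful threshold.
#' @param abund_meanlog,abund_sdlog log-normal abundance parameters
#'   (individuals per sample).
#' @param sparse_autumn if `TRUE`, autumn samples at sites K3 and K5 are
#'   thinned to 0-1 species, emulating empty/single-species samples from
#'   which no effect size can be derived.
#' @param seed master RNG seed; every stage draws a named sub-seed from it.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("neutral", "filtering", "limiting"),
                          n_species = 24,
                          distances_m = c(0, 500, 2500, 3000, 3500),
                          n_dates_per_season = 3,
                          filter_strength = 40,
                          axis = c("functional", "phylogenetic"),
                          min_dist = 0.10,
                          richness_range = NULL,
                          abund_meanlog = 3, abund_sdlog = 1,
                          sparse_autumn = FALSE,
                          seed = 1) {
  scenario <- match.arg(scenario)
  axis <- match.arg(axis)
  if (is.null(richness_range)) {
    richness_range <- if (scenario == "limiting") 3:4 else 5:15
    richness_range <- richness_range[richness_range <= n_species]
    if (length(richness_range) == 0) richness_range <- n_species
  }
  stopifnot(n_species >= 3, all(diff(distances_m) > 0), all(distances_m >= 0),
    filter_strength >= 0, min_dist >= 0, all(richness_range >= 1))
  if (max(richness_range) > n_species) {
    stopf("richness_range exceeds the pool size (%d)", n_species)
  }
  structure(list(
    scenario = scenario, n_species = n_species, distances_m = distances_m,
    n_dates_per_season = n_dates_per_season, filter_strength = filter_strength,
    axis = axis, min_dist = min_dist,
    richness_range = richness_range,
    abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
    sparse_autumn = sparse_autumn, seed = seed
  ), class = "scenario_spec")
}

#' Simulate a Yule (pure-birth) species tree
#'
#' The tree is scaled to a root-to-tip depth of `depth` substitutions/site
#' (default 0.2, a plausible COI divergence scale) and unrooted.
#'
#' @param n_species number of leaves (>= 3).
#' @param seed integer RNG seed.
#' @param depth root-to-tip depth after scaling.
#' @return an unrooted `phylo` tree with tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_species, seed, depth = 0.2) {
  stopifnot(n_species >= 3)
  set.seed(sub_seed(seed, "tree"))
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / h
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  ape::unroot(tr)
}

#' Simulate aligned sequences on a tree under the K2P model
#'
#' Sites evolve independently under the Kimura two-parameter substitution
#' process (equal base frequencies, transition/transversion rate ratio
#' `kappa`), with branch lengths in expected substitutions per site. The
#' default length of 621 sites matches a COI barcode fragment.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param length alignment length in sites.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param seed integer RNG seed.
#' @return an `aligned_sequences` object.
#' @export
simulate_sequences <- function(tree, length = 621, kappa = 2, seed = 1) {
  stopifnot(length >= 1, kappa > 0)
  set.seed(sub_seed(seed, "seq"))
  sim <- phangorn::simSeq(tree, l = length,
    Q = c(1, kappa, 1, 1, kappa, 1), bf = rep(0.25, 4))
  m <- toupper(as.character(sim))
  aligned_sequences(vapply(seq_len(nrow(m)), function(i) {
    paste(m[i, ], collapse = "")
  }, character(1), USE.NAMES = FALSE) |> stats::setNames(rownames(m)))
}

#' Simulate a conserved trait table on a tree
#'
#' Body size is exp(Brownian motion) rescaled to 50-1500 um; each
#' categorical and ordinal trait evolves by an equal-rates continuous-time
#' Markov jump process on the same tree, so related species share similar
#' traits and the functional and phylogenetic distance matrices are
#' positively correlated. With `conservatism = "none"` traits are
#' simulated on a copy of the tree with shuffled tips, preserving trait
#' distributions but destroying the phylogenetic signal.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param seed integer RNG seed.
#' @param conservatism `"phylogenetic"` (default) or `"none"`.
#' @param changes_per_lineage expected number of state changes root-to-tip
#'   for the discrete traits (controls conservatism strength).
#' @return a `trait_table`.
#' @export
simulate_traits <- function(tree, seed = 1,
                            conservatism = c("phylogenetic", "none"),
                            changes_per_lineage = 1.2) {
  conservatism <- match.arg(conservatism)
  set.seed(sub_seed(seed, "traits"))
  sim_tree <- tree
  if (conservatism == "none") {
    sim_tree$tip.label <- sample(tree$tip.label)
  }
  depth <- max(ape::node.depth.edgelength(sim_tree))
  schema <- trait_schema()

  z <- ape::rTraitCont(sim_tree, model = "BM", sigma = 1)
  if (diff(range(z)) < 1e-12) {
    body <- rep(sqrt(50 * 1500), length(z))
  } else {
    body <- exp(log(50) + (z - min(z)) / diff(range(z)) * (log(1500) - log(50)))
  }
  names(body) <- sim_tree$tip.label

  sim_disc <- function(levels) {
    k <- length(levels)
    rate <- if (depth > 0) changes_per_lineage / ((k - 1) * depth) else 0
    if (rate == 0) {
      st <- rep(levels[1], length(sim_tree$tip.label))
      names(st) <- sim_tree$tip.label
      return(st)
    }
    x <- ape::rTraitDisc(sim_tree, model = "ER", k = k, rate = rate,
      states = levels)
    stats::setNames(as.character(x), names(x))
  }

  df <- data.frame(species = tree$tip.label)
  df$body_size_um <- body[df$species]
  for (tr in setdiff(names(schema), "body_size_um")) {
    v <- sim_disc(schema[[tr]]$levels)
    df[[tr]] <- v[df$species]
  }
  trait_table(df)
}

## The assembly rules measure each species' position directly in the
## chosen distance matrix. The environmental optimum is the pool medoid
## (minimum summed distance to all others), so a strongly filtered
## community is a tight neighbourhood around it and its pairwise
## distances — hence its MPD — are compressed relative to the pool.
pool_medoid <- function(m) rownames(m)[which.min(rowSums(m))]

#' Assemble communities under a known rule along the distance gradient
#'
#' For every site x season x date, a target richness is drawn, species are
#' selected from the pool according to the scenario, and log-normal
#' abundances are attached. Selection rules:
#' \describe{
#'   \item{neutral}{species drawn uniformly without replacement.}
#'   \item{filtering}{inclusion probability proportional to
#'     exp(-s(site) * delta_i^2), where delta_i is the species' distance
#'     (in the chosen matrix) to the environmental optimum — the pool
#'     medoid — and the site strength s decays linearly from
#'     `filter_strength` at 0 m to 0 at the farthest site.}
#'   \item{limiting}{sequential assembly in random order, rejecting any
#'     candidate within `min_dist` (on the chosen axis) of a resident;
#'     failure to reach the target richness is an error suggesting a
#'     smaller threshold.}
#' }
#' Richness and abundance values are drawn from sub-streams independent of
#' the scenario, so scenarios with the same seed share them.
#'
#' @param tree the species tree.
#' @param traits a `trait_table` for the pool.
#' @param spec a [scenario_spec()].
#' @return a `community_matrix`.
#' @export
assemble_communities <- function(tree, traits, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!setequal(tree$tip.label, traits$species)) {
    stopf("tree and trait table disagree on species labels")
  }
  pool <- sort(traits$species)
  n <- length(pool)
  axis_m <- if (spec$axis == "functional") {
    gower_matrix(traits)[pool, pool]
  } else {
    standardize_unit(patristic_matrix(tree))[pool, pool]
  }
  delta <- axis_m[, pool_medoid(axis_m)]   # distance to the site optimum
  sites <- sprintf("K%d", seq_along(spec$distances_m))
  max_d <- max(spec$distances_m)

  rows <- list()
  for (si in seq_along(sites)) {
    strength <- spec$filter_strength * (1 - spec$distances_m[si] / max_d)
    for (se in SEASONS) {
      dates <- if (spec$n_dates_per_season == 3) STUDY_DATES[[se]] else
        sprintf("2016-%02d-%02d", match(se, SEASONS) * 3 + 1,
          seq_len(spec$n_dates_per_season))
      for (dt in dates) {
        id <- paste(sites[si], se, dt, sep = "|")
        set.seed(sub_seed(spec$seed, paste0("rich|", id)))
        k <- sample(spec$richness_range, 1)
        set.seed(sub_seed(spec$seed, paste0("pick|", id)))
        chosen <- switch(spec$scenario,
          neutral = pool[sample.int(n, k)],
          filtering = {
            if (strength == 0) {          # no filter left: same draw as neutral
              pool[sample.int(n, k)]
            } else {
              pool[sample.int(n, k, prob = exp(-strength * delta^2))]
            }
          },
          limiting = {
            ord <- sample.int(n)
            acc <- integer(0)
            for (cand in ord) {
              if (length(acc) == 0 ||
                  min(axis_m[cand, acc]) > spec$min_dist) {
                acc <- c(acc, cand)
              }
              if (length(acc) == k) break
            }
            if (length(acc) < k) {
              stopf(paste("limiting-similarity assembly cannot reach richness %d",
                "at %s with min_dist = %g; use a smaller threshold"),
                k, id, spec$min_dist)
            }
            pool[acc]
          })
        set.seed(sub_seed(spec$seed, paste0("abund|", id)))
        av <- ceiling(stats::rlnorm(k, spec$abund_meanlog, spec$abund_sdlog))
        if (spec$sparse_autumn && se == "autumn" && sites[si] %in% c("K3", "K5")) {
          keep <- seq_len(if (sites[si] == "K5") 0 else 1)  # empty / singleton
          chosen <- chosen[keep]
          av <- av[keep]
        }
        ab <- stats::setNames(numeric(n), pool)
        ab[chosen] <- av
        rows[[id]] <- data.frame(site = sites[si], date = dt, season = se,
          distance_m = spec$distances_m[si], t(ab), check.names = FALSE)
      }
    }
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  community_matrix(df)
}

#' Simulate a complete synthetic study
#'
#' Convenience bundle: tree, sequences, traits and communities that are
#' mutually consistent and pass all the package readers' validation.
#'
#' @param spec a [scenario_spec()].
#' @param seq_length alignment length.
#' @param kappa transition/transversion ratio for sequence simulation.
#' @param conservatism passed to [simulate_traits()].
#' @return list with `tree`, `alignment`, `traits`, `communities`, `truth`
#'   (the scenario parameters).
#' @export
simulate_study <- function(spec = scenario_spec(), seq_length = 621,
                           kappa = 2, conservatism = "phylogenetic") {
  tree <- simulate_tree(spec$n_species, spec$seed)
  aln <- simulate_sequences(tree, length = seq_length, kappa = kappa,
    seed = spec$seed)
  traits <- simulate_traits(tree, seed = spec$seed, conservatism = conservatism)
  cm <- assemble_communities(tree, traits, spec)
  truth <- unclass(spec)
  truth$conservatism <- conservatism
  truth$site_filter_strength <- spec$filter_strength *
    (1 - spec$distances_m / max(spec$distances_m))
  list(tree = tree, alignment = aln, traits = traits, communities = cm,
    truth = truth)
}

#' Write a simulated study to a directory
#'
#' Emits `traits.csv`, `alignment.fasta`, `abundance.csv`, `tree.nwk` and
#' `truth.json`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trait_table(study$traits, file.path(dir, "traits.csv"))
  write_alignment(study$alignment, file.path(dir, "alignment.fasta"))
  write_community_matrix(study$communities, file.path(dir, "abundance.csv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
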