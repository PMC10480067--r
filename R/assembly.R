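## Community-assembly inference: abundance-weighted mean pairwise distance,
## randomization null models, probit-transformed effect sizes, the alpha
## sweep selecting the blend weight with maximal explanatory power, and
## Rao's quadratic entropy.

#' Abundance-weighted mean pairwise distance (MPD)
#'
#' MPD = sum_{i<j} d_ij a_i a_j / sum_{i<j} a_i a_j over species with
#' positive abundance. Weighting by abundance reduces the influence of
#' rare species on the community's mean distance.
#'
#' @param d distance matrix over the species pool.
#' @param abund abundance vector named by (or aligned with) the pool labels.
#' @return the weighted MPD, or `NA` when fewer than 2 species are present.
#' @export
weighted_mpd <- function(d, abund) {
  a <- align_abund(d, abund)
  pres <- which(a > 0)
  if (length(pres) < 2) return(NA_real_)
  av <- a[pres]
  ds <- d[pres, pres]
  num <- sum(ds * outer(av, av))              # = 2 * sum over i<j
  den <- sum(av)^2 - sum(av^2)
  num / den
}

align_abund <- function(d, abund) {
  if (!is.null(names(abund))) {
    miss <- setdiff(names(abund)[abund > 0], rownames(d))
    if (length(miss)) stopf("species missing from distance matrix: %s", toString(miss))
    a <- stats::setNames(numeric(nrow(d)), rownames(d))
    a[names(abund)] <- abund
    a
  } else {
    if (length(abund) != nrow(d)) stopf("abundance length does not match pool")
    stats::setNames(abund, rownames(d))
  }
}

#' Null distribution of the weighted MPD under random assembly
#'
#' Each replicate draws as many species as the sample contains, uniformly
#' without replacement from the regional pool (all labels of `d`), keeps
#' the sample's observed abundance values (identities are randomized, the
#' abundance vector is preserved), and recomputes the weighted MPD. This
#' holds species richness constant per sample, the standard
#' richness-constrained randomization.
#'
#' @inheritParams weighted_mpd
#' @param n_null number of randomizations (study default 999).
#' @param seed integer RNG seed.
#' @return numeric vector of `n_null` null MPD values.
#' @export
null_mpd_distribution <- function(d, abund, n_null, seed) {
  a <- align_abund(d, abund)
  pres <- which(a > 0)
  k <- length(pres)
  n <- nrow(d)
  if (k < 2) stopf("sample has fewer than 2 species present")
  if (n < k) stopf("pool (%d) smaller than sample richness (%d)", n, k)
  av <- a[pres]
  set.seed(seed)
  vapply(seq_len(n_null), function(r) {
    idx <- sample.int(n, k)
    ds <- d[idx, idx]
    sum(ds * outer(av, av)) / (sum(av)^2 - sum(av^2))
  }, numeric(1))
}

#' Probit-transformed effect size of an observed value against its null
#'
#' The observed value's quantile position in the null distribution is
#' converted to a p-value with ties split, p = (k + (t + 1)/2) / (n + 1)
#' where k counts null values below the observation and t counts ties, and
#' mapped through the standard-normal quantile function: ES = qnorm(p).
#' This makes no normality assumption about the null. Negative values
#' indicate the observation sits low in the null mass (environmental
#' filtering when applied to MPD); positive values indicate it sits high
#' (limiting similarity / biotic interactions).
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics.
#' @return the effect size (finite by construction).
#' @export
probit_es <- function(observed, null) {
  n <- length(null)
  if (n == 0) stopf("empty null distribution")
  k <- sum(null < observed)
  t <- sum(null == observed)
  stats::qnorm((k + (t + 1) / 2) / (n + 1))
}

#' Mean effect size with percentile bootstrap confidence interval
#'
#' @param es_values effect sizes (NAs are dropped).
#' @param n_boot bootstrap resamples (study default 999).
#' @param seed integer RNG seed.
#' @param conf confidence level (default 0.95).
#' @return named vector `mean`, `lower`, `upper` (all `NA` when no finite
#'   value remains; degenerate `(v, v, v)` for a single value).
#' @export
mean_es_ci <- function(es_values, n_boot = 999, seed = 1, conf = 0.95) {
  x <- es_values[is.finite(es_values)]
  if (length(x) == 0) {
    return(c(mean = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  if (length(x) == 1) return(c(mean = x, lower = x, upper = x))
  set.seed(seed)
  means <- vapply(seq_len(n_boot), function(b) {
    mean(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  qs <- stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(mean = mean(x), lower = qs[1], upper = qs[2])
}

#' Rao's quadratic entropy
#'
#' Q = sum_i sum_j d_ij p_i p_j with p the relative abundances: the
#' expected distance between two individuals drawn at random (with
#' replacement) from the community.
#'
#' @inheritParams weighted_mpd
#' @return Q; 0 for a single-species sample, `NA` for an empty one.
#' @export
rao_q <- function(d, abund) {
  a <- align_abund(d, abund)
  tot <- sum(a)
  if (tot <= 0) return(NA_real_)
  p <- a / tot
  pres <- which(p > 0)
  sum(d[pres, pres] * outer(p[pres], p[pres]))
}

## Per-sample null machinery, precomputed once so the same randomized
## identities are reused for every alpha of the sweep (paired seeding:
## without it the argmax over 41 Monte-Carlo-noisy curves is unstable).
## For each sample we store linear indices into the pool distance matrix
## for the observed community and for every null replicate, plus the
## flattened abundance weight vector, so MPD under any blended matrix D is
## a single indexed sum.
prep_sample_nulls <- function(cm, pool, n_null, seed) {
  ab <- comm_abundance(cm)
  n <- length(pool)
  lapply(seq_len(nrow(cm)), function(i) {
    a <- ab[i, pool]
    pres <- which(a > 0)
    k <- length(pres)
    if (k < 2) return(list(k = k))
    av <- unname(a[pres])
    wvec <- rep(av, times = k) * rep(av, each = k)
    W <- sum(av)^2 - sum(av^2)
    lin <- function(idx) (rep(idx, each = k) - 1L) * n + rep(idx, times = k)
    sample_id <- paste(cm$site[i], cm$date[i], sep = "|")
    set.seed(sub_seed(seed, paste0("null|", sample_id)))
    LIN <- t(vapply(seq_len(n_null), function(r) lin(sample.int(n, k)),
      integer(k * k)))
    list(k = k, obs_lin = lin(pres), wvec = wvec, W = W, LIN = LIN)
  })
}

sample_es_from_prep <- function(D, prep) {
  vapply(prep, function(p) {
    if (p$k < 2) return(NA_real_)
    obs <- sum(D[p$obs_lin] * p$wvec) / p$W
    null <- as.numeric(matrix(D[p$LIN], nrow = nrow(p$LIN)) %*% p$wvec) / p$W
    probit_es(obs, null)
  }, numeric(1))
}

#' Per-sample effect sizes for one blended distance matrix
#'
#' Computes the abundance-weighted MPD of every sample, its
#' richness-constrained null distribution over the regional pool, and the
#' probit effect size. Samples with fewer than 2 species present get
#' `NA` (flagged in the `defined` column).
#'
#' @param d distance matrix over the regional species pool.
#' @param cm a `community_matrix` whose species are all in `d`.
#' @param n_null randomizations per sample.
#' @param seed master seed; each sample uses a sub-seed derived from its
#'   site and date, so results are independent of sample order.
#' @return data frame with site, date, season, distance_m, n_species,
#'   mpd_obs, es, defined.
#' @export
sample_es <- function(d, cm, n_null = 999, seed = 1) {
  pool <- comm_species(cm)
  miss <- setdiff(pool, rownames(d))
  if (length(miss)) stopf("species missing from distance matrix: %s", toString(miss))
  d <- d[pool, pool]
  prep <- prep_sample_nulls(cm, pool, n_null, seed)
  ab <- comm_abundance(cm)
  es <- sample_es_from_prep(d, prep)
  mpd <- vapply(seq_len(nrow(cm)), function(i) weighted_mpd(d, ab[i, pool]),
    numeric(1))
  data.frame(
    site = cm$site, date = cm$date, season = cm$season,
    distance_m = cm$distance_m,
    n_species = rowSums(ab > 0),
    mpd_obs = mpd, es = es, defined = is.finite(es),
    row.names = NULL
  )
}

#' Sweep the blend weight and select the alpha with maximal explanatory power
#'
#' For every alpha on the grid, the phylogenetic and functional matrices
#' are blended ([fp_distance()]), per-sample effect sizes are computed
#' against the richness-constrained null (the same null identities are
#' reused across the grid), and an ordinary least-squares model
#' ES ~ sampling position is fitted per season, pooling that season's
#' dates. The optimal alpha per season is the grid point maximizing the
#' adjusted R-squared; ties resolve to the smallest alpha.
#'
#' @param pd,fd phylogenetic and functional distance matrices over (at
#'   least) the community's species pool, entries in \[0, 1\].
#' @param cm a `community_matrix`.
#' @param config a [pipeline_config()] list (alpha grid, rho, null and
#'   bootstrap counts, seed, position scale).
#' @return an `alpha_sweep` list: `sweep` (season x alpha adjusted R^2,
#'   slope, intercept), `optimal` (per-season optimal alpha), `es`
#'   (per-sample ES at the season's optimal alpha), `site_summary`
#'   (per-site mean ES with bootstrap CI), `rao` (per-sample Rao's Q at
#'   the optimal alpha).
#' @export
alpha_sweep <- function(pd, fd, cm, config = pipeline_config()) {
  pool <- comm_species(cm)
  for (nm in c("pd", "fd")) {
    m <- get(nm)
    miss <- setdiff(pool, rownames(m))
    if (length(miss)) stopf("%s is missing species: %s", toupper(nm), toString(miss))
  }
  pd <- pd[pool, pool]
  fd <- fd[pool, pool]
  grid <- config$alpha_grid
  seasons <- intersect(SEASONS, unique(cm$season))
  ab <- comm_abundance(cm)

  prep <- prep_sample_nulls(cm, pool, config$n_null, config$seed)
  pos <- if (config$position == "rank") {
    as.numeric(factor(rank(cm$distance_m, ties.method = "min")))
  } else {
    cm$distance_m
  }

  ## ES for every sample at every alpha (paired nulls across the grid)
  es_grid <- matrix(NA_real_, nrow(cm), length(grid))
  blends <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    D <- fp_distance(pd, fd, grid[g], config$rho)
    blends[[g]] <- D
    es_grid[, g] <- sample_es_from_prep(D, prep)
  }

  sweep_rows <- list()
  opt_rows <- list()
  es_rows <- list()
  site_rows <- list()
  rao_rows <- list()
  for (se in seasons) {
    rows <- which(cm$season == se)
    fit_stats <- t(vapply(seq_along(grid), function(g) {
      y <- es_grid[rows, g]
      x <- pos[rows]
      ok <- is.finite(y)
      if (sum(ok) < 3) return(c(NA_real_, NA_real_, NA_real_))
      fit <- stats::lm(y[ok] ~ x[ok])
      s <- summary(fit)
      c(s$adj.r.squared, stats::coef(fit)[2], stats::coef(fit)[1])
    }, numeric(3)))
    sweep_rows[[se]] <- data.frame(
      season = se, alpha = grid, adj_r2 = fit_stats[, 1],
      slope = fit_stats[, 2], intercept = fit_stats[, 3],
      n_samples = sum(is.finite(es_grid[rows, 1]))
    )
    if (all(is.na(fit_stats[, 1]))) {
      warning(sprintf("season %s: too few samples with defined ES; no optimal alpha", se))
      opt_rows[[se]] <- data.frame(season = se, alpha_optimal = NA_real_,
        adj_r2 = NA_real_)
      next
    }
    g_opt <- which.max(fit_stats[, 1])   # first maximum = smallest alpha
    a_opt <- grid[g_opt]
    opt_rows[[se]] <- data.frame(season = se, alpha_optimal = a_opt,
      adj_r2 = fit_stats[g_opt, 1])
    D <- blends[[g_opt]]
    es_rows[[se]] <- data.frame(
      site = cm$site[rows], date = cm$date[rows], season = se,
      distance_m = cm$distance_m[rows],
      n_species = rowSums(ab[rows, , drop = FALSE] > 0),
      alpha = a_opt, es = es_grid[rows, g_opt]
    )
    for (st in unique(cm$site[rows])) {
      srows <- rows[cm$site[rows] == st]
      ci <- mean_es_ci(es_grid[srows, g_opt], config$n_boot,
        sub_seed(config$seed, paste0("boot|", se, "|", st)))
      site_rows[[paste(se, st)]] <- data.frame(
        season = se, site = st, distance_m = cm$distance_m[srows][1],
        mean_es = ci[["mean"]], ci_lo = ci[["lower"]], ci_hi = ci[["upper"]],
        n_dates = sum(is.finite(es_grid[srows, g_opt]))
      )
    }
    rao_rows[[se]] <- data.frame(
      site = cm$site[rows], date = cm$date[rows], season = se,
      distance_m = cm$distance_m[rows], alpha = a_opt,
      rao_q = vapply(rows, function(i) {
        a <- ab[i, pool]
        if (sum(a > 0) == 0) NA_real_ else rao_q(D, a)
      }, numeric(1))
    )
  }
  structure(list(
    sweep = do.call(rbind, c(sweep_rows, list(make.row.names = FALSE))),
    optimal = do.call(rbind, c(opt_rows, list(make.row.names = FALSE))),
    es = do.call(rbind, c(es_rows, list(make.row.names = FALSE))),
    site_summary = do.call(rbind, c(site_rows, list(make.row.names = FALSE))),
    rao = do.call(rbind, c(rao_rows, list(make.row.names = FALSE)))
  ), class = "alpha_sweep")
}
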