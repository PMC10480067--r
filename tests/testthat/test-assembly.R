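test_that("weighted MPD matches hand-evaluated cases and stays within bounds", {
  d2 <- distance_matrix(matrix(c(0, 0.6, 0.6, 0), 2, 2), c("a", "b"))
  expect_equal(weighted_mpd(d2, c(a = 5, b = 1)), 0.6)

  d3 <- distance_matrix(matrix(c(0, 0.2, 0.4, 0.2, 0, 0.6, 0.4, 0.6, 0), 3, 3),
    c("a", "b", "c"))
  expect_equal(weighted_mpd(d3, c(a = 1, b = 1, c = 1)), 0.4)

  d3b <- distance_matrix(matrix(c(0, 0.3, 0.3, 0.3, 0, 0.9, 0.3, 0.9, 0), 3, 3),
    c("a", "b", "c"))
  expect_equal(weighted_mpd(d3b, c(a = 2, b = 1, c = 1)),
    (2 * 0.3 + 2 * 0.3 + 1 * 0.9) / 5)

  expect_true(is.na(weighted_mpd(d3, c(a = 3, b = 0, c = 0))))

  # bounds property over random inputs
  for (s in 1:50) {
    d <- random_distance_matrix(7, 5000 + s)
    a <- setNames(rexp(7), rownames(d))
    a[sample(7, 2)] <- 0
    pres <- names(a)[a > 0]
    sub <- d[pres, pres]
    v <- weighted_mpd(d, a)
    expect_gte(v, min(sub[upper.tri(sub)]))
    expect_lte(v, max(sub[upper.tri(sub)]))
  }
})

test_that("null MPD distribution matches exhaustive enumeration on a tiny pool", {
  d <- distance_matrix(matrix(c(0, 0.2, 0.7, 0.2, 0, 0.4, 0.7, 0.4, 0), 3, 3),
    c("a", "b", "c"))
  abund <- c(a = 3, b = 1, c = 0)   # richness 2 from a 3-species pool
  # enumeration: every ordered pair of distinct species, abundances (3, 1)
  pairs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  enum <- apply(pairs, 1, function(ij) d[ij[1], ij[2]])  # single pair: MPD = d_ij
  null <- null_mpd_distribution(d, abund, n_null = 10000, seed = 8)
  near <- function(x, v) abs(x - v) < 1e-12
  expect_true(all(vapply(null, function(x) any(near(x, unique(enum))), logical(1))))
  for (v in unique(enum)) {
    expect_equal(mean(near(null, v)), mean(near(enum, v)), tolerance = 0.02)
  }
  # constant distances: degenerate null
  dc <- distance_matrix(matrix(0.5, 3, 3) - 0.5 * diag(3), c("a", "b", "c"))
  expect_true(all(null_mpd_distribution(dc, abund, 100, 1) == 0.5))
  expect_error(null_mpd_distribution(d[1:2, 1:2], c(a = 1, b = 1, c = 1), 10, 1),
    "missing|pool")
})

test_that("probit effect sizes hit the closed-form quantile values", {
  null <- seq_len(999) / 1000
  expect_equal(probit_es(0, null), qnorm(0.0005), tolerance = 1e-12)
  expect_equal(probit_es(1, null), qnorm(0.9995), tolerance = 1e-12)
  expect_equal(probit_es(0, null), -probit_es(1, null), tolerance = 1e-12)
  expect_equal(probit_es(null[500], null), 0, tolerance = 1e-12)
})

test_that("effect sizes of observations drawn from their own null are standard normal", {
  set.seed(31)
  es <- vapply(1:300, function(i) {
    d <- random_distance_matrix(10, 20000 + i)
    a <- setNames(c(ceiling(rlnorm(5, 2, 1)), rep(0, 5)), rownames(d))
    vals <- null_mpd_distribution(d, a, n_null = 200, seed = 40000 + i)
    probit_es(vals[1], vals[-1])
  }, numeric(1))
  expect_lt(abs(mean(es)), 0.15)
  rate <- mean(abs(es) > 1.96)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("mean ES bootstrap CI behaves at the edges and covers the truth", {
  expect_equal(unname(mean_es_ci(2.5, 99, 1)), c(2.5, 2.5, 2.5))
  ci <- mean_es_ci(c(-1, 0, 1), 999, 2)
  expect_equal(ci[["mean"]], 0)
  expect_gte(ci[["lower"]], -1)
  expect_lte(ci[["upper"]], 1)
  expect_true(all(is.na(mean_es_ci(c(NA_real_, NA_real_), 99, 1))))

  set.seed(77)
  cover <- vapply(1:200, function(i) {
    x <- rnorm(300)
    ci <- mean_es_ci(x, n_boot = 299, seed = i)
    ci[["lower"]] <= 0 && 0 <= ci[["upper"]]
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("rao_q matches a brute-force double sum and its invariances", {
  d2 <- distance_matrix(matrix(c(0, 1, 1, 0), 2, 2), c("a", "b"))
  expect_equal(rao_q(d2, c(a = 1, b = 1)), 0.5)
  expect_equal(rao_q(d2, c(a = 1, b = 0)), 0)
  expect_true(is.na(rao_q(d2, c(a = 0, b = 0))))

  for (s in 1:100) {
    n <- sample(3:9, 1)
    d <- random_distance_matrix(n, 6000 + s)
    a <- setNames(rexp(n), rownames(d))
    q <- rao_q(d, a)
    expect_equal(q, rao_oracle(d, a), tolerance = 1e-12)
    expect_equal(rao_q(d, 2 * a), q, tolerance = 1e-12)
    expect_lte(q, max(d))
  }
})

test_that("sample_es flags undefined samples and is order-stable", {
  st <- simulate_study(scenario_spec("neutral", seed = 5, sparse_autumn = TRUE))
  cm <- st$communities
  pool <- comm_species(cm)
  fd <- gower_matrix(st$traits)[pool, pool]
  tab <- sample_es(fd, cm, n_null = 99, seed = 5)
  k5a <- tab[tab$site == "K5" & tab$season == "autumn", ]
  expect_true(all(!k5a$defined))
  expect_true(all(is.na(k5a$es)))
  k3a <- tab[tab$site == "K3" & tab$season == "autumn", ]
  expect_true(all(k3a$n_species == 1))
  expect_true(all(tab$defined[tab$season == "spring"]))

  # per-sample sub-seeding: reordering samples does not change any ES
  perm <- sample(nrow(cm))
  tab2 <- sample_es(fd, community_matrix(as.data.frame(cm)[perm, ]),
    n_null = 99, seed = 5)
  merged <- merge(tab, tab2, by = c("site", "date"))
  expect_equal(merged$es.x, merged$es.y)
})

test_that("alpha sweep at a degenerate or two-point grid is consistent with fp_distance", {
  st <- simulate_study(scenario_spec("filtering", seed = 9))
  cm <- st$communities
  pool <- sort(comm_species(cm))
  fd <- gower_matrix(st$traits)[pool, pool]
  pd <- standardize_unit(patristic_matrix(st$tree))[pool, pool]

  cfg1 <- pipeline_config(seed = 9, alpha_grid = 0.5, n_null = 99, n_boot = 99,
    n_mantel = 0, n_tree_boot = 0)
  sw1 <- alpha_sweep(pd, fd, cm, cfg1)
  expect_true(all(sw1$optimal$alpha_optimal == 0.5))

  cfg2 <- pipeline_config(seed = 9, alpha_grid = c(0, 1), n_null = 99,
    n_boot = 99, n_mantel = 0, n_tree_boot = 0)
  sw2 <- alpha_sweep(pd, fd, cm, cfg2)
  # alpha = 0 rows equal a pure-FDist analysis, alpha = 1 pure PDist
  es_f <- sample_es(fd, cm, n_null = 99, seed = 9)
  es_p <- sample_es(pd, cm, n_null = 99, seed = 9)
  for (se in unique(cm$season)) {
    rows <- sw2$sweep[sw2$sweep$season == se, ]
    fit_f <- summary(lm(es ~ distance_m, data = es_f[es_f$season == se, ]))
    fit_p <- summary(lm(es ~ distance_m, data = es_p[es_p$season == se, ]))
    expect_equal(rows$adj_r2[rows$alpha == 0], fit_f$adj.r.squared,
      tolerance = 1e-10)
    expect_equal(rows$adj_r2[rows$alpha == 1], fit_p$adj.r.squared,
      tolerance = 1e-10)
  }
})

test_that("a season without enough defined effect sizes yields an NA optimum", {
  st <- simulate_study(scenario_spec("neutral", seed = 6))
  cm <- st$communities
  df <- as.data.frame(cm)
  sp <- comm_species(cm)
  df[df$season == "autumn", sp] <- 0   # every autumn sample empty
  cm2 <- community_matrix(df)
  pool <- sort(comm_species(cm2))
  fd <- gower_matrix(st$traits)[pool, pool]
  pd <- standardize_unit(patristic_matrix(st$tree))[pool, pool]
  cfg <- pipeline_config(seed = 6, alpha_grid = c(0, 0.5), n_null = 49,
    n_boot = 49, n_mantel = 0, n_tree_boot = 0)
  expect_warning(sw <- alpha_sweep(pd, fd, cm2, cfg), "autumn")
  expect_true(is.na(sw$optimal$alpha_optimal[sw$optimal$season == "autumn"]))
  expect_false(anyNA(sw$optimal$alpha_optimal[sw$optimal$season != "autumn"]))
})
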