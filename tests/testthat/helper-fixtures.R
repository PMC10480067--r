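# Fixture builders and independent oracle implementations used across the
# suite. The oracles deliberately share no code with the package internals.

valid_trait_df <- function() {
  data.frame(
    species = c("brachionus_a", "keratella_b", "asplanchna_c"),
    body_size_um = c(150, 250, 900),
    trophi_type = c("malleate", "malleate", "incudate"),
    feeding_type = c("microphagous", "microphagous", "macrophagous_predator"),
    protection = c("passive", "passive", "active"),
    lorica_type = c("loricate_ridged", "loricate_spined", "illoricate"),
    corona_type = c("euchlanis_brachionus", "euchlanis_brachionus", "asplanchna"),
    habitat_preference = c("beta-mesosaprobic", "beta-mesosaprobic",
      "oligo/beta-mesosaprobic"),
    tolerance = c(4, 3, 2),
    stringsAsFactors = FALSE
  )
}

random_trait_df <- function(n, seed, na_frac = 0) {
  set.seed(seed)
  schema <- trait_schema()
  df <- data.frame(species = sprintf("sp%02d", seq_len(n)))
  df$body_size_um <- round(exp(runif(n, log(50), log(1500))), 1)
  for (tr in setdiff(names(schema), "body_size_um")) {
    df[[tr]] <- sample(schema[[tr]]$levels, n, replace = TRUE)
  }
  if (na_frac > 0) {
    for (tr in names(schema)) {
      hit <- runif(n) < na_frac
      df[[tr]][hit] <- NA
    }
  }
  df
}

# Independent Gower oracle: explicit per-trait loops, no shared encoding.
gower_oracle <- function(df, i, j) {
  schema <- trait_schema()
  parts <- c()
  for (tr in names(schema)) {
    a <- df[[tr]][i]; b <- df[[tr]][j]
    if (is.na(a) || is.na(b)) next
    kind <- schema[[tr]]$kind
    if (kind == "categorical") {
      parts <- c(parts, if (a == b) 0 else 1)
    } else {
      va <- if (kind == "numeric") as.numeric(df[[tr]]) else
        match(as.character(df[[tr]]), schema[[tr]]$levels)
      rng <- max(va, na.rm = TRUE) - min(va, na.rm = TRUE)
      d <- abs(va[i] - va[j])
      parts <- c(parts, if (rng > 0) d / rng else 0)
    }
  }
  mean(parts)
}

# Independent Rao oracle: naive double loop.
rao_oracle <- function(d, a) {
  p <- a / sum(a)
  q <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) q <- q + d[i, j] * p[[i]] * p[[j]]
  }
  unname(q)
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  distance_matrix(m, sprintf("t%02d", seq_len(n)))
}

# Additive distance matrix from a random tree with strictly positive
# branch lengths, plus the generating tree for topology comparison.
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, d = distance_matrix(stats::cophenetic(tr)))
}

tiny_alignment <- function() {
  aligned_sequences(c(
    a = "ACGTACGTACGT",
    b = "ACGTACGTACGA",
    c = "ACGTTCGTACGA"
  ))
}
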