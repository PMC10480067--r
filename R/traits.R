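## Functional (Gower) distances over the mixed trait table.

## Per-trait partial distances for a pair of records:
##   numeric / ordinal: |a - b| / range of the trait over the whole table
##                      (zero range => partial distance 0)
##   categorical:       0 if equal, 1 otherwise
## The overall distance is the mean of partial distances over traits where
## both records have a value; an NA trait is dropped from that pair only.
## Ordinal traits (habitat preference, tolerance) enter as integer ranks
## with range normalisation — the classic Gower treatment of ordered
## variables. All eight traits carry equal weight.

## Encode the trait table numerically once: numeric traits as-is, ordinal
## as rank, categorical as level index (compared only for equality).
encode_traits <- function(tt) {
  schema <- trait_schema()
  enc <- matrix(NA_real_, nrow(tt), length(schema),
    dimnames = list(tt$species, names(schema)))
  kind <- vapply(schema, `[[`, "", "kind")
  for (tr in names(schema)) {
    v <- tt[[tr]]
    enc[, tr] <- if (schema[[tr]]$kind == "numeric") as.numeric(v)
      else as.numeric(match(as.character(v), schema[[tr]]$levels))
  }
  rng <- rep(NA_real_, length(schema))
  names(rng) <- names(schema)
  for (tr in names(schema)[kind != "categorical"]) {
    rng[tr] <- diff(range(enc[, tr], na.rm = TRUE))
  }
  list(enc = enc, kind = kind, range = rng)
}

gower_pair_encoded <- function(a, b, kind, rng) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stopf("no shared non-missing traits for this pair")
  part <- numeric(sum(ok))
  k <- kind[ok]; aa <- a[ok]; bb <- b[ok]; rr <- rng[ok]
  cat_i <- k == "categorical"
  part[cat_i] <- as.numeric(aa[cat_i] != bb[cat_i])
  num_i <- !cat_i
  d <- abs(aa[num_i] - bb[num_i])
  r <- rr[num_i]
  part[num_i] <- ifelse(r > 0, d / r, 0)
  mean(part)
}

#' Gower distance between two species' trait records
#'
#' @param tt a `trait_table` (ranges for numeric and ordinal traits are
#'   computed over this whole table).
#' @param a,b species labels present in `tt`.
#' @return a distance in \[0, 1\].
#' @export
gower_pair <- function(tt, a, b) {
  e <- encode_traits(tt)
  if (!all(c(a, b) %in% rownames(e$enc))) stopf("unknown species label")
  gower_pair_encoded(e$enc[a, ], e$enc[b, ], e$kind, e$range)
}

#' Functional distance matrix (FDist) from a trait table
#'
#' Pairwise Gower distances over the eight-trait schema; see [gower_pair()]
#' for the per-trait conventions.
#'
#' @param tt a `trait_table` with at least two species.
#' @return a species-by-species distance matrix with entries in \[0, 1\].
#' @export
gower_matrix <- function(tt) {
  if (nrow(tt) < 2) stopf("need at least 2 species")
  e <- encode_traits(tt)
  n <- nrow(e$enc)
  m <- matrix(0, n, n, dimnames = list(rownames(e$enc), rownames(e$enc)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- gower_pair_encoded(
        e$enc[i, ], e$enc[j, ], e$kind, e$range)
    }
  }
  distance_matrix(m)
}
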