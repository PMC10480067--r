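## Trait schema -------------------------------------------------------------

#' Trait schema for the rotifer trait table
#'
#' Eight ecological and morphological traits are used: geometric-mean body
#' size (micrometres), trophi (jaw) type, feeding type, predator protection,
#' lorica (body wall) type, corona type (named after characteristic genera),
#' saprobic habitat preference (ordered) and saprobic tolerance (1 narrow to
#' 5 wide, ordered). The schema records each trait's kind (numeric,
#' categorical, or ordinal) and, for closed-vocabulary traits, its levels —
#' in rank order for ordinal traits.
#'
#' @return a named list, one entry per trait, with elements `kind` and
#'   (except for numeric traits) `levels`.
#' @export
trait_schema <- function() {
  list(
    body_size_um = list(kind = "numeric"),
    trophi_type = list(kind = "categorical", levels = c(
      "malleate", "virgate", "ramate", "incudate", "malleoramate", "forcipate"
    )),
    feeding_type = list(kind = "categorical", levels = c(
      "microphagous", "polyphagous", "macrophagous_algivore",
      "macrophagous_predator"
    )),
    protection = list(kind = "categorical", levels = c("active", "passive")),
    lorica_type = list(kind = "categorical", levels = c(
      "illoricate", "loricate_ridged", "loricate_spined"
    )),
    corona_type = list(kind = "categorical", levels = c(
      "asplanchna", "philodina", "euchlanis_brachionus", "notommata",
      "dichranophorus", "conochilus", "hexarthra_testudinella", "collotheca"
    )),
    habitat_preference = list(kind = "ordinal", levels = c(
      "oligosaprobic", "oligo/beta-mesosaprobic", "beta-mesosaprobic",
      "beta/alpha-mesosaprobic"
    )),
    tolerance = list(kind = "ordinal", levels = as.character(1:5))
  )
}

#' Build and validate a trait table
#'
#' @param df data frame with a `species` column plus the eight trait columns
#'   of [trait_schema()].
#' @return a `trait_table`: a data frame with species as rows, validated
#'   against the schema.
#' @export
trait_table <- function(df) {
  schema <- trait_schema()
  need <- c("species", names(schema))
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("trait table missing columns: %s", toString(miss))
  df <- as.data.frame(df)[need]
  df$species <- as.character(df$species)
  if (anyDuplicated(df$species)) {
    stopf("duplicate species labels: %s",
      toString(unique(df$species[duplicated(df$species)])))
  }
  df$body_size_um <- as.numeric(df$body_size_um)
  bad <- which(!is.na(df$body_size_um) & df$body_size_um <= 0)
  if (length(bad)) stopf("nonpositive body_size_um in row(s) %s", toString(bad))
  df$tolerance <- as.character(df$tolerance)
  for (tr in names(schema)) {
    sc <- schema[[tr]]
    if (sc$kind == "numeric") next
    vals <- as.character(df[[tr]])
    bad <- which(!is.na(vals) & !vals %in% sc$levels)
    if (length(bad)) {
      stopf("unknown %s value %s in row %d (species %s)",
        tr, dQuote(vals[bad[1]]), bad[1], df$species[bad[1]])
    }
    df[[tr]] <- vals
  }
  rownames(df) <- df$species
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming a `species`
#' column and the eight traits of [trait_schema()]. Vocabulary and range
#' violations are reported with the offending row and column.
#'
#' @param path path to the CSV file.
#' @return a `trait_table`.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  trait_table(df)
}

#' @rdname read_trait_table
#' @param tt a `trait_table`.
#' @export
write_trait_table <- function(tt, path) {
  utils::write.csv(as.data.frame(tt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Alignment ----------------------------------------------------------------

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased and must be of equal length, with unique
#' headers and at least two records. Symbols outside A, C, G, T, N, - are
#' rejected.
#'
#' @param path path to a FASTA file.
#' @return an `aligned_sequences` object: a named character vector of
#'   equal-length nucleotide strings.
#' @export
read_alignment <- function(path) {
  bin <- ape::read.FASTA(path)
  if (length(bin) == 0) stopf("empty FASTA file: %s", path)
  seqs <- vapply(as.character(bin), function(x) paste(toupper(x), collapse = ""),
    character(1))
  aligned_sequences(seqs)
}

#' @rdname read_alignment
#' @param seqs named character vector of nucleotide strings.
#' @export
aligned_sequences <- function(seqs) {
  if (length(seqs) < 2) stopf("alignment needs at least 2 sequences")
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stopf("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stopf("duplicate sequence header: %s",
      toString(unique(names(seqs)[duplicated(names(seqs))])))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    off <- names(seqs)[lens != lens[1]][1]
    stopf("unequal sequence lengths: %s has %d sites, %s has %d",
      names(seqs)[1], lens[1], off, lens[match(off, names(seqs))])
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stopf("invalid alignment symbol(s): %s", toString(bad))
  structure(seqs, class = "aligned_sequences")
}

#' @rdname read_alignment
#' @param aln an `aligned_sequences` object.
#' @export
write_alignment <- function(aln, path) {
  bin <- ape::as.DNAbin(lapply(strsplit(unclass(aln), ""), tolower))
  ape::write.FASTA(bin, path)
  invisible(path)
}

## Community matrix ---------------------------------------------------------

META_COLS <- c("site", "date", "season", "distance_m")
SEASONS <- c("spring", "summer", "autumn")

#' Build and validate a sample-by-species community matrix
#'
#' Each row is one sample (a site visited on a date); metadata columns
#' `site`, `date`, `season`, `distance_m` are followed by one abundance
#' column per species. Abundances must be nonnegative, seasons must be
#' spring/summer/autumn, and `distance_m` must be constant within a site.
#'
#' @param df wide data frame (metadata columns then species columns).
#' @return a `community_matrix` data frame.
#' @export
community_matrix <- function(df) {
  df <- as.data.frame(df)
  miss <- setdiff(META_COLS, names(df))
  if (length(miss)) stopf("community matrix missing columns: %s", toString(miss))
  df <- df[c(META_COLS, setdiff(names(df), META_COLS))]
  df$site <- as.character(df$site)
  df$date <- as.character(df$date)
  df$season <- as.character(df$season)
  bad <- setdiff(unique(df$season), SEASONS)
  if (length(bad)) stopf("unknown season label(s): %s", toString(bad))
  df$distance_m <- as.numeric(df$distance_m)
  if (any(is.na(df$distance_m) | df$distance_m < 0)) {
    stopf("distance_m must be nonnegative")
  }
  for (s in unique(df$site)) {
    dd <- unique(df$distance_m[df$site == s])
    if (length(dd) > 1) {
      stopf("site %s has inconsistent distance_m values: %s", s, toString(dd))
    }
  }
  sp <- setdiff(names(df), META_COLS)
  if (length(sp) == 0) stopf("community matrix has no species columns")
  for (col in sp) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(is.na(df[[col]]) | df[[col]] < 0)) {
      stopf("negative or missing abundance in species column %s", col)
    }
  }
  class(df) <- c("community_matrix", "data.frame")
  df
}

#' @rdname community_matrix
#' @param path path to a CSV file.
#' @export
read_community_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  community_matrix(df)
}

#' @rdname community_matrix
#' @param cm a `community_matrix`.
#' @export
write_community_matrix <- function(cm, path) {
  utils::write.csv(as.data.frame(cm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Species columns of a community matrix
#' @param cm a `community_matrix`.
#' @return for [comm_species()], the species labels; for [comm_abundance()],
#'   the numeric sample-by-species abundance matrix with sample ids
#'   `site|date` as rownames.
#' @export
comm_species <- function(cm) setdiff(names(cm), META_COLS)

#' @rdname comm_species
#' @export
comm_abundance <- function(cm) {
  a <- as.matrix(as.data.frame(cm)[comm_species(cm)])
  rownames(a) <- paste(cm$site, cm$date, sep = "|")
  a
}
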