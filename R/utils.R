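# Shared helpers: the abundance-table container, Dirichlet draws, rounding.

ALPHABET <- c("A", "C", "G", "T", "N", "-")

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIX <- c(
  domain = "k__", phylum = "p__", class = "c__", order = "o__",
  family = "f__", genus = "g__", species = "s__"
)

ABUND_LEVELS <- c(
  "domain", "phylum", "class", "order", "family", "genus", "species",
  "otu97", "oligotype"
)

#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed report tables use the
#' conventional half-away-from-zero rule (e.g. a coefficient of variation of
#' 47.5 prints as 48).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Draw from a Dirichlet distribution
#'
#' Standard gamma construction. Used by the synthetic community generator for
#' individual profiles and per-sample fluctuations.
#'
#' @param n Number of draws.
#' @param alpha Concentration vector (all > 0).
#' @return An `n` x `length(alpha)` matrix whose rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  stopifnot(n >= 1, length(alpha) >= 1, all(alpha > 0))
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Construct an abundance table
#'
#' The package's central tabular container: a long tibble with one row per
#' (sample, taxon) pair carrying a relative abundance (or a count, for count
#' tables), plus per-sample `individual` and `timepoint` labels where known.
#' The taxonomic `level` of the taxa is recorded as an attribute.
#'
#' @param x A data frame with columns `sample`, `taxon`, `abundance` and
#'   optionally `individual`, `timepoint`.
#' @param level Taxonomic level of the rows, one of
#'   `r paste(ABUND_LEVELS, collapse = ", ")`.
#' @return A tibble of class `abund_tbl`.
#' @export
abund_table <- function(x, level) {
  level <- match.arg(level, ABUND_LEVELS)
  x <- as_tibble(x)
  need <- c("sample", "taxon", "abundance")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "abundance table lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(x$abundance < 0)) abort("abundances must be non-negative")
  if (anyDuplicated(x[c("sample", "taxon")]) > 0) {
    abort("duplicated (sample, taxon) rows in abundance table")
  }
  structure(x, level = level, class = c("abund_tbl", class(as_tibble(x))))
}

#' Taxonomic level of an abundance table
#' @param x An `abund_tbl`.
#' @return A string.
#' @export
abund_level <- function(x) attr(x, "level") %||% NA_character_

# keep class/attrs across dplyr verbs used internally
restore_abund <- function(out, template) {
  abund_table(out, level = abund_level(template))
}

#' Widen an abundance table to a samples x taxa matrix
#'
#' @param x An `abund_tbl` (or any tibble with sample/taxon/abundance).
#' @param fill Value for absent (sample, taxon) pairs.
#' @return A numeric matrix, samples as rows.
#' @export
abund_matrix <- function(x, fill = 0) {
  wide <- tidyr::pivot_wider(
    as_tibble(x)[c("sample", "taxon", "abundance")],
    names_from = "taxon", values_from = "abundance", values_fill = fill
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample
  m
}

#' Rebuild an abundance table from a samples x taxa matrix
#'
#' @param m Numeric matrix with sample rownames and taxon colnames.
#' @param level Taxonomic level to record.
#' @param meta Optional tibble with `sample`, `individual`, `timepoint` to
#'   re-attach per-sample labels.
#' @return An `abund_tbl`.
#' @export
abund_from_matrix <- function(m, level, meta = NULL) {
  long <- tibble(
    sample = rep(rownames(m), times = ncol(m)),
    taxon = rep(colnames(m), each = nrow(m)),
    abundance = as.vector(m)
  )
  if (!is.null(meta)) {
    long <- left_join(long, as_tibble(meta), by = "sample")
  }
  abund_table(long, level = level)
}

#' Per-sample metadata of an abundance table
#' @param x An `abund_tbl` with `individual` (and optionally `timepoint`).
#' @return A tibble with one row per sample.
#' @export
sample_meta <- function(x) {
  cols <- intersect(c("sample", "individual", "timepoint"), names(x))
  distinct(as_tibble(x)[cols])
}

# complete the (sample x taxon) grid with zero abundance, preserving
# metadata; returns a plain tibble (works on any sample/taxon/abundance df)
complete_grid <- function(x) {
  m <- abund_matrix(x, fill = 0)
  long <- tibble(
    sample = rep(rownames(m), times = ncol(m)),
    taxon = rep(colnames(m), each = nrow(m)),
    abundance = as.vector(m)
  )
  meta_cols <- intersect(c("sample", "individual", "timepoint"), names(x))
  if (length(meta_cols) > 1) {
    long <- left_join(long, distinct(as_tibble(x)[meta_cols]), by = "sample")
  }
  long
}

# character matrix (one row per sequence) from equal-width strings
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0) return(matrix(character(), 0, 0))
  w <- unique(nchar(seqs))
  if (length(w) != 1) abort("sequences are not all the same length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE
  )
}

# number of mismatching columns between each sequence and a reference string
seq_mismatches <- function(seqs, ref) {
  if (length(seqs) == 0) return(integer())
  cm <- seq_char_matrix(c(ref, seqs))
  colSums(t(cm[-1, , drop = FALSE]) != cm[1, ])
}

#' Parse a semicolon-delimited lineage string
#'
#' Lineages follow the common `k__...;p__...;...;s__...` convention with up
#' to seven ranks (domain to species). Trailing ranks may be absent
#' (truncated lineages) or empty.
#'
#' @param lineage Character vector of lineage strings.
#' @return A tibble with one row per lineage and one column per rank
#'   (`NA` where unresolved).
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  out <- lapply(TAX_RANKS, function(rank) {
    prefix <- RANK_PREFIX[[rank]]
    vapply(parts, function(p) {
      p <- trimws(p)
      hit <- p[startsWith(p, prefix)]
      if (length(hit) == 0) return(NA_character_)
      val <- sub(prefix, "", hit[1], fixed = TRUE)
      if (nzchar(val)) val else NA_character_
    }, character(1))
  })
  names(out) <- TAX_RANKS
  as_tibble(out)
}

# build a lineage string from rank values (NA ranks dropped from the tail)
make_lineage <- function(domain, phylum = NA, class = NA, order = NA,
                         family = NA, genus = NA, species = NA) {
  vals <- c(domain, phylum, class, order, family, genus, species)
  keep <- seq_len(max(which(!is.na(vals)), 1))
  paste0(RANK_PREFIX[keep], ifelse(is.na(vals[keep]), "", vals[keep]),
    collapse = ";"
  )
}
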