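# Relative-abundance tables, the >1% mean-abundance filter, de novo 97% OTU
# binning of oligotype representatives, and shared-taxon harmonization
# across data sets.

#' Convert a count table to relative abundances
#'
#' @param counts Long tibble `sample`, `taxon`, `count` (or `abundance`).
#' @param level Taxonomic level to record on the result.
#' @param meta Optional per-sample metadata tibble (`sample`, `individual`,
#'   `timepoint`) to attach.
#' @return An [abund_table()] with a complete (sample x taxon) grid; each
#'   sample's abundances sum to 1.
#' @export
to_relative <- function(counts, level, meta = NULL) {
  counts <- as_tibble(counts)
  if (!"abundance" %in% names(counts)) {
    counts <- rename(counts, abundance = "count")
  }
  tbl <- abund_table(counts[c("sample", "taxon", "abundance")], level = level)
  m <- abund_matrix(tbl)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort(paste0(
      "sample(s) with zero total count: ",
      paste(head(rownames(m)[totals == 0], 5), collapse = ", ")
    ))
  }
  meta <- meta %||% (if (all(c("individual") %in% names(counts))) {
    distinct(counts[intersect(c("sample", "individual", "timepoint"), names(counts))])
  } else {
    NULL
  })
  abund_from_matrix(m / totals, level = level, meta = meta)
}

#' Keep taxa above a mean relative abundance threshold
#'
#' Keeps taxa whose mean relative abundance over all samples is strictly
#' greater than `threshold` (the "greater than 1%" rule at the default),
#' ordered by decreasing mean. Absent (sample, taxon) pairs count as zeros.
#'
#' @param x An `abund_tbl` of relative abundances.
#' @param threshold Fraction (default 0.01).
#' @return The filtered `abund_tbl`; per-taxon means are attached as the
#'   `taxon_means` attribute.
#' @export
mean_abundance_filter <- function(x, threshold = 0.01) {
  stopifnot(threshold >= 0)
  m <- abund_matrix(x)
  means <- sort(colMeans(m), decreasing = TRUE)
  keep <- names(means)[means > threshold]
  out <- abund_from_matrix(
    m[, keep, drop = FALSE],
    level = abund_level(x), meta = sample_meta(x)
  )
  out$taxon <- factor(out$taxon, levels = keep)
  out <- arrange(out, .data$taxon, .data$sample)
  out$taxon <- as.character(out$taxon)
  out <- abund_table(out, level = abund_level(x))
  attr(out, "taxon_means") <- means
  out
}

# identity over shared non-terminal-gap columns of two equal-length
# aligned sequences
aligned_identity <- function(ca, cb) {
  nga <- which(ca != "-")
  ngb <- which(cb != "-")
  if (length(nga) == 0 || length(ngb) == 0) return(NA_real_)
  lo <- max(nga[1], ngb[1])
  hi <- min(nga[length(nga)], ngb[length(ngb)])
  if (lo > hi) return(NA_real_)
  idx <- lo:hi
  sum(ca[idx] == cb[idx]) / length(idx)
}

#' Bin oligotypes into 97% OTUs
#'
#' Greedy abundance-ordered centroid clustering of aligned, equal-length
#' representative sequences: seeds are taken in decreasing total-abundance
#' order; each remaining oligotype joins the first existing bin containing
#' any member at or above the identity threshold (single-linkage admission,
#' first-bin priority), otherwise it founds a new bin.
#'
#' @param x A `med_result`, or a tibble with `node_id`, `representative` and
#'   optionally `n_reads`.
#' @param threshold Identity threshold as a fraction (default 0.97).
#' @return Tibble `node_id`, `otu_id`, `seed` (logical: founded the bin).
#' @export
bin_otus_97 <- function(x, threshold = 0.97) {
  nodes <- if (inherits(x, "med_result")) x$nodes else as_tibble(x)
  if (nrow(nodes) == 0) {
    return(tibble(node_id = character(), otu_id = character(), seed = logical()))
  }
  if (length(unique(nchar(nodes$representative))) != 1) {
    abort("representatives are not all the same length")
  }
  abund <- if ("n_reads" %in% names(nodes)) nodes$n_reads else rep(1, nrow(nodes))
  ord <- order(-abund, nodes$node_id)
  cm <- seq_char_matrix(nodes$representative)
  bins <- list() # each: integer vector of row indices (in original order)
  bin_of <- integer(nrow(nodes))
  for (i in ord) {
    placed <- FALSE
    for (b in seq_along(bins)) {
      members <- bins[[b]]
      hit <- any(vapply(
        members,
        function(j) {
          id <- aligned_identity(cm[i, ], cm[j, ])
          !is.na(id) && id >= threshold
        },
        logical(1)
      ))
      if (hit) {
        bins[[b]] <- c(members, i)
        bin_of[i] <- b
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      bins[[length(bins) + 1]] <- i
      bin_of[i] <- length(bins)
    }
  }
  seeds <- vapply(bins, function(members) members[1], integer(1))
  tibble(
    node_id = nodes$node_id,
    otu_id = sprintf("OTU%03d", bin_of),
    seed = seq_len(nrow(nodes)) %in% seeds
  )
}

#' Collapse node counts to 97% OTUs
#'
#' @param counts Long tibble `node_id`, `sample`, `count`.
#' @param otu_map A [bin_otus_97()] tibble.
#' @return Long tibble `sample`, `taxon` (= otu_id), `count`.
#' @export
collapse_otus <- function(counts, otu_map) {
  as_tibble(counts) |>
    left_join(otu_map[c("node_id", "otu_id")], by = "node_id") |>
    group_by(sample = .data$sample, taxon = .data$otu_id) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Restrict several abundance tables to their shared taxa
#'
#' Intersects the taxon sets of two or more same-level tables and restricts
#' each table to the intersection, without renormalizing (abundances remain
#' fractions of the whole community). The summed mean abundance excluded
#' from each table is reported in the `excluded` attribute.
#'
#' @param tables Named (or unnamed) list of `abund_tbl`s at the same level.
#' @return List of restricted `abund_tbl`s with an `excluded` attribute
#'   (tibble: table, excluded_mean).
#' @export
subset_shared_taxa <- function(tables) {
  stopifnot(length(tables) >= 2)
  levels <- vapply(tables, abund_level, character(1))
  if (length(unique(levels)) != 1) {
    abort("tables are not all at the same taxonomic level")
  }
  taxa_sets <- lapply(tables, function(t) unique(t$taxon))
  shared <- Reduce(intersect, taxa_sets)
  if (length(shared) == 0) abort("no taxa shared between tables")
  nm <- names(tables) %||% paste0("table", seq_along(tables))
  nm[!nzchar(nm)] <- paste0("table", which(!nzchar(nm)))
  out <- lapply(tables, function(t) {
    restore_abund(filter(as_tibble(t), .data$taxon %in% shared), t)
  })
  excluded <- tibble(
    table = nm,
    excluded_mean = vapply(unname(tables), function(t) {
      m <- abund_matrix(t)
      drop_cols <- setdiff(colnames(m), shared)
      mean(rowSums(m[, drop_cols, drop = FALSE]))
    }, numeric(1))
  )
  names(out) <- nm
  attr(out, "excluded") <- excluded
  out
}
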