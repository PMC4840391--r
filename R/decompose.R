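# Minimum-entropy decomposition of an aligned read set into oligotypes.
#
# The algorithm: starting from a single node holding all reads, repeatedly
# split any node whose maximum column-wise Shannon entropy exceeds the
# threshold m, partitioning its reads by the residue at the highest-entropy
# column. After convergence two noise filters run in order: the minimum
# substantive abundance criterion (discard a node when its most frequent
# unique sequence has fewer than M copies) and the maximum variation allowed
# criterion (remove reads differing from the node representative at more
# than V columns). Read accounting is exact:
# n_input = n_retained + n_removed_min_abundance + n_removed_max_variation.

#' Shannon entropy of one alignment column
#'
#' Entropy in bits (log base 2) over the residue states (A, C, G, T, N, -)
#' present in the column, optionally weighting each sequence by a read count.
#'
#' @param seqs Character vector of equal-length gapped sequences.
#' @param column 1-based column index.
#' @param weights Optional non-negative read counts, one per sequence.
#' @return Entropy in bits (0 for a single-state column).
#' @export
#' @examples
#' column_entropy(c("AA", "AC"), 2) # 1 bit
column_entropy <- function(seqs, column, weights = NULL) {
  if (length(seqs) == 0) abort("empty sequence set")
  w <- unique(nchar(seqs))
  if (length(w) != 1) abort("sequences are not all the same length")
  if (column < 1 || column > w) {
    abort(paste0("column ", column, " out of range 1..", w))
  }
  weights <- weights %||% rep(1, length(seqs))
  chars <- substring(seqs, column, column)
  tab <- tapply(weights, chars, sum)
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}

# entropy of every column for a weighted set of rows of a character matrix
column_entropies <- function(cm, weights) {
  total <- sum(weights)
  p <- vapply(
    ALPHABET,
    function(s) colSums(weights * (cm == s)) / total,
    numeric(ncol(cm))
  )
  if (ncol(cm) == 1) p <- matrix(p, nrow = 1)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(plogp)
}

#' Representative sequence of a node
#'
#' The most frequent unique member sequence; ties broken by taking the
#' lexicographically smallest.
#'
#' @param seqs Character vector of unique member sequences.
#' @param n Read count of each unique sequence.
#' @return A single sequence string.
#' @export
node_representative <- function(seqs, n) {
  if (length(seqs) == 0) abort("empty node")
  stopifnot(length(seqs) == length(n))
  best <- which(n == max(n))
  sort(seqs[best])[1]
}

#' Minimum substantive abundance filter
#'
#' A node is discarded in full (all its reads counted as removed) when the
#' copy number of its most frequent unique member sequence is below `M`.
#'
#' @param nodes List of node tibbles, each with columns `seq` (unique
#'   sequences) and `n` (read counts).
#' @param M Minimum substantive abundance (default 60).
#' @return List with `keep` (logical per node) and `n_removed` (reads lost).
#' @export
filter_min_abundance <- function(nodes, M = 60) {
  stopifnot(M >= 1)
  top <- vapply(nodes, function(nd) max(nd$n), numeric(1))
  keep <- top >= M
  n_removed <- sum(vapply(nodes[!keep], function(nd) sum(nd$n), numeric(1)))
  list(keep = keep, n_removed = as.integer(n_removed))
}

#' Maximum variation allowed filter
#'
#' Removes reads that differ from the node representative at more than `V`
#' alignment columns (a gap opposite a base counts as a difference).
#'
#' @param node Tibble with columns `seq` (unique sequences) and `n` (counts).
#' @param V Maximum number of mismatch columns tolerated (default 3).
#' @return List with `node` (filtered tibble), `representative`, and
#'   `n_removed` (reads lost).
#' @export
filter_max_variation <- function(node, V = 3) {
  stopifnot(V >= 0)
  rep_seq <- node_representative(node$seq, node$n)
  dists <- seq_mismatches(node$seq, rep_seq)
  keep <- dists <= V
  list(
    node = node[keep, ],
    representative = rep_seq,
    n_removed = as.integer(sum(node$n[!keep]))
  )
}

#' Minimum entropy decomposition into oligotypes
#'
#' Iteratively partitions an aligned read set on high-entropy columns, then
#' applies the minimum-substantive-abundance (`M`) and
#' maximum-variation-allowed (`V`) noise filters. Surviving nodes are
#' renamed `OT001`, `OT002`, ... in decreasing total-abundance order.
#'
#' @param x An [aligned_reads()] object (rectangular), or a tibble with
#'   columns `read_id`, `sample`, `seq`.
#' @param M Minimum substantive abundance criterion (default 60).
#' @param V Maximum variation allowed criterion, in columns (default 3).
#' @param m Entropy threshold in bits below which a node stops splitting
#'   (default 0.0965).
#' @return An object of class `med_result`: a list with `nodes` (tibble of
#'   node_id, representative, n_reads, top_count, max_entropy), `counts`
#'   (long tibble node_id x sample), `assignments` (read_id to node_id for
#'   retained reads), `accounting`, `params`, and `samples` metadata.
#' @export
med_decompose <- function(x, M = 60, V = 3, m = 0.0965) {
  stopifnot(M >= 1, V >= 0, m >= 0)
  if (inherits(x, "aligned_reads")) {
    reads <- x$reads
    samples <- x$samples
  } else {
    reads <- as_tibble(x)
    samples <- distinct(reads[intersect(
      c("sample", "individual", "timepoint"), names(reads)
    )])
  }
  params <- list(M = M, V = V, m = m, entropy_base = "log2")
  if (nrow(reads) == 0) {
    return(new_med_result(
      nodes = tibble(
        node_id = character(), representative = character(),
        n_reads = integer(), top_count = integer(), max_entropy = numeric()
      ),
      counts = tibble(node_id = character(), sample = character(), count = integer()),
      assignments = tibble(read_id = character(), node_id = character()),
      accounting = list(
        n_input = 0L, n_retained = 0L,
        n_removed_min_abundance = 0L, n_removed_max_variation = 0L
      ),
      params = params, samples = samples
    ))
  }

  # collapse to unique sequences; decomposition depends only on the multiset
  useq <- sort(unique(reads$seq))
  uidx <- match(reads$seq, useq)
  w <- tabulate(uidx, nbins = length(useq))
  cm <- seq_char_matrix(useq)

  # iterative entropy splitting over unique-sequence index sets
  stack <- list(seq_along(useq))
  leaves <- list()
  leaf_maxent <- numeric()
  while (length(stack) > 0) {
    idx <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ent <- column_entropies(cm[idx, , drop = FALSE], w[idx])
    maxent <- max(ent)
    if (maxent > m && length(idx) > 1) {
      col <- which.max(ent) # ties: lowest column index
      children <- split(idx, cm[idx, col])
      stack <- c(stack, unname(children))
    } else {
      leaves[[length(leaves) + 1]] <- idx
      leaf_maxent <- c(leaf_maxent, maxent)
    }
  }

  node_tbls <- lapply(leaves, function(idx) tibble(uid = idx, seq = useq[idx], n = w[idx]))

  # filter 1: minimum substantive abundance (whole-node removal)
  fa <- filter_min_abundance(node_tbls, M)
  node_tbls <- node_tbls[fa$keep]
  leaf_maxent <- leaf_maxent[fa$keep]

  # filter 2: maximum variation (per-read outlier removal)
  n_removed_v <- 0L
  reps <- character(length(node_tbls))
  for (i in seq_along(node_tbls)) {
    fv <- filter_max_variation(node_tbls[[i]], V)
    node_tbls[[i]] <- fv$node
    reps[i] <- fv$representative
    n_removed_v <- n_removed_v + fv$n_removed
  }

  sizes <- vapply(node_tbls, function(nd) sum(nd$n), numeric(1))
  ord <- order(-sizes, reps)
  node_tbls <- node_tbls[ord]
  reps <- reps[ord]
  sizes <- sizes[ord]
  leaf_maxent <- leaf_maxent[ord]
  ids <- sprintf("OT%03d", seq_along(node_tbls))

  uid_node <- rep(NA_character_, length(useq))
  for (i in seq_along(node_tbls)) uid_node[node_tbls[[i]]$uid] <- ids[i]
  read_node <- uid_node[uidx]
  retained <- !is.na(read_node)

  counts <- tibble(
    node_id = read_node[retained],
    sample = reads$sample[retained]
  ) |>
    count(.data$node_id, .data$sample, name = "count")

  nodes <- tibble(
    node_id = ids,
    representative = reps,
    n_reads = as.integer(sizes),
    top_count = vapply(node_tbls, function(nd) as.integer(max(nd$n)), integer(1)),
    max_entropy = leaf_maxent
  )

  accounting <- list(
    n_input = nrow(reads),
    n_retained = as.integer(sum(sizes)),
    n_removed_min_abundance = fa$n_removed,
    n_removed_max_variation = n_removed_v
  )

  new_med_result(
    nodes = nodes,
    counts = counts,
    assignments = tibble(
      read_id = reads$read_id[retained],
      node_id = read_node[retained]
    ),
    accounting = accounting, params = params, samples = samples
  )
}

new_med_result <- function(nodes, counts, assignments, accounting, params,
                           samples) {
  structure(
    list(
      nodes = nodes, counts = counts, assignments = assignments,
      accounting = accounting, params = params, samples = samples
    ),
    class = "med_result"
  )
}

#' @export
print.med_result <- function(x, ...) {
  a <- x$accounting
  cat(
    "<med_result> ", nrow(x$nodes), " oligotypes from ", a$n_input,
    " reads (retained ", a$n_retained,
    ", removed M ", a$n_removed_min_abundance,
    ", removed V ", a$n_removed_max_variation, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Write decomposition artifacts
#'
#' Emits the node-by-sample count matrix (TSV), the representative sequences
#' (FASTA) and a JSON run report with the read-accounting integers and
#' parameters.
#'
#' @param x A `med_result`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_med_result <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_path <- file.path(dir, "node_counts.tsv")
  fasta_path <- file.path(dir, "representatives.fasta")
  report_path <- file.path(dir, "med_report.json")
  wide <- tidyr::pivot_wider(
    x$counts,
    names_from = "sample", values_from = "count", values_fill = 0L
  )
  readr::write_tsv(wide, mat_path)
  ss <- Biostrings::BStringSet(
    setNames(x$nodes$representative, x$nodes$node_id)
  )
  Biostrings::writeXStringSet(ss, fasta_path)
  jsonlite::write_json(
    list(accounting = x$accounting, params = x$params),
    report_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(mat_path, fasta_path, report_path))
}
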