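# Best-hit taxonomy assignment of oligotype representatives by global
# (Needleman-Wunsch) alignment against a lineage-annotated reference, and
# collapse of node count matrices to any taxonomic rank.

default_submat <- function(match = 5, mismatch = -4) {
  states <- c("A", "C", "G", "T", "N")
  sm <- matrix(mismatch, 5, 5, dimnames = list(states, states))
  diag(sm) <- match
  sm["N", "N"] <- mismatch # N never counts as a match
  sm
}

#' Global pairwise alignment of two sequences
#'
#' Needleman-Wunsch optimal global alignment with match +5, mismatch -4 and
#' a linear gap penalty of -10 (the scoring is conventional for DNA; the
#' downstream statistic is percent identity, which is insensitive to any
#' reasonable scheme). Gap characters are stripped from the inputs first.
#'
#' @param a,b Sequences (character strings).
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `aligned_a`, `aligned_b` (equal-length gapped strings)
#'   and `score`.
#' @export
#' @examples
#' global_align("ACGT", "AGT")
global_align <- function(a, b, match = 5, mismatch = -4, gap = -10) {
  a <- gsub("-", "", a, fixed = TRUE)
  b <- gsub("-", "", b, fixed = TRUE)
  if (!nzchar(a) || !nzchar(b)) abort("empty sequence in global_align")
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = default_submat(match, mismatch),
    gapOpening = 0, gapExtension = -gap
  )
  list(
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

#' Percent identity of an aligned sequence pair
#'
#' 100 x matches / aligned columns, where columns lying in a terminal gap of
#' either sequence are excluded (so partial-length references are not
#' penalized) and internal gap columns count as mismatches.
#'
#' @param aligned_a,aligned_b Equal-length aligned (gapped) strings.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned sequences differ in length")
  }
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  span <- function(x) {
    ng <- which(x != "-")
    if (length(ng) == 0) c(NA_integer_, NA_integer_) else range(ng)
  }
  sa <- span(ca)
  sb <- span(cb)
  lo <- max(sa[1], sb[1])
  hi <- min(sa[2], sb[2])
  if (is.na(lo) || is.na(hi) || lo > hi) {
    abort("no comparable columns (alignment is all terminal gap)")
  }
  idx <- lo:hi
  100 * sum(ca[idx] == cb[idx] & ca[idx] != "-") / length(idx)
}

#' Assign a lineage to one representative sequence
#'
#' Aligns the representative against every reference; the best hit is the
#' maximal percent identity. When several references tie, the lineage is
#' truncated to the deepest rank at which all tied references agree.
#'
#' @param representative Gapped or ungapped sequence string.
#' @param refdb A [read_reference()] tibble.
#' @param tie_tol Identity difference treated as a tie (default 1e-9).
#' @return One-row tibble: `lineage`, `percent_identity`, `n_best_hits`.
#' @export
assign_lineage <- function(representative, refdb, tie_tol = 1e-9) {
  stopifnot(nrow(refdb) > 0)
  query <- gsub("-", "", representative, fixed = TRUE)
  if (!nzchar(query)) abort("empty representative sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = refdb$seq, subject = query, type = "global",
    substitutionMatrix = default_submat(), gapOpening = 0, gapExtension = 10
  )
  arefs <- as.character(Biostrings::alignedPattern(pa))
  aqrys <- as.character(Biostrings::alignedSubject(pa))
  pid <- vapply(
    seq_len(nrow(refdb)),
    function(i) percent_identity(aqrys[i], arefs[i]),
    numeric(1)
  )
  best <- which(pid >= max(pid) - tie_tol)
  if (length(best) == 1) {
    lineage <- refdb$lineage[best]
  } else {
    ranks <- parse_lineage(refdb$lineage[best])
    agree <- vapply(
      ranks,
      function(col) !anyNA(col) && length(unique(col)) == 1,
      logical(1)
    )
    depth <- if (all(agree)) length(agree) else min(which(!agree)) - 1L
    if (depth == 0) {
      lineage <- RANK_PREFIX[["domain"]] # unresolved even at domain
    } else {
      vals <- as.character(ranks[1, seq_len(depth)])
      lineage <- paste0(RANK_PREFIX[seq_len(depth)], vals, collapse = ";")
    }
  }
  tibble(
    lineage = lineage,
    percent_identity = max(pid),
    n_best_hits = length(best)
  )
}

#' Assign lineages to all oligotypes of a decomposition
#'
#' @param x A `med_result` or a tibble with `node_id` and `representative`.
#' @param refdb A [read_reference()] tibble.
#' @return Tibble with one row per node: `node_id`, `lineage`,
#'   `percent_identity`, `n_best_hits`, plus parsed rank columns.
#' @export
assign_taxonomy <- function(x, refdb) {
  nodes <- if (inherits(x, "med_result")) x$nodes else as_tibble(x)
  out <- purrr::map_dfr(seq_len(nrow(nodes)), function(i) {
    bind_cols(
      tibble(node_id = nodes$node_id[i]),
      assign_lineage(nodes$representative[i], refdb)
    )
  })
  bind_cols(out, parse_lineage(out$lineage))
}

#' Collapse a node count matrix to a taxonomic rank
#'
#' Sums node counts by the lineage value at the requested rank. Nodes
#' unresolved at that rank are pooled under their deepest resolved name with
#' an `_unclassified` suffix. `level = "oligotype"` is the identity.
#'
#' @param counts Long tibble `node_id`, `sample`, `count` (e.g.
#'   `med_result$counts`).
#' @param assignments An [assign_taxonomy()] tibble.
#' @param level One of domain, phylum, class, order, family, genus, species,
#'   oligotype.
#' @return Long tibble `sample`, `taxon`, `count`.
#' @export
collapse_counts <- function(counts, assignments,
                            level = c(
                              "genus", "phylum", "species", "oligotype",
                              "domain", "class", "order", "family"
                            )) {
  level <- match.arg(level)
  counts <- as_tibble(counts)
  if (level == "oligotype") {
    return(counts |>
      transmute(
        sample = .data$sample, taxon = .data$node_id,
        count = .data$count
      ))
  }
  missing_nodes <- setdiff(unique(counts$node_id), assignments$node_id)
  if (length(missing_nodes) > 0) {
    abort(paste0(
      "node(s) without assignment: ",
      paste(head(missing_nodes, 5), collapse = ", ")
    ))
  }
  ranks <- parse_lineage(assignments$lineage)
  target <- ranks[[level]]
  deepest <- apply(ranks, 1, function(r) {
    resolved <- which(!is.na(r) & nzchar(r))
    if (length(resolved) == 0) "Unassigned" else r[max(resolved)]
  })
  taxon <- ifelse(is.na(target), paste0(deepest, "_unclassified"), target)
  map <- tibble(node_id = assignments$node_id, taxon = taxon)
  counts |>
    left_join(map, by = "node_id") |>
    group_by(.data$sample, .data$taxon) |>
    summarise(count = sum(.data$count), .groups = "drop")
}
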