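# Aligned-FASTA and sample-map I/O plus the pre-decomposition cleanup rules:
# fixed-length trimming and removal of gap-only alignment columns.

#' Construct an aligned read set
#'
#' Container for a rectangular (equal-width, gapped) amplicon alignment with
#' per-read sample labels and per-sample individual/timepoint labels.
#'
#' @param reads Tibble with columns `read_id`, `sample`, `seq`.
#' @param samples Tibble with columns `sample`, `individual`, `timepoint`.
#' @param allow_ragged If `FALSE` (default), unequal sequence lengths are an
#'   error; set `TRUE` only when [trim_to_length()] will be applied next.
#' @return An object of class `aligned_reads`.
#' @export
aligned_reads <- function(reads, samples, allow_ragged = FALSE) {
  reads <- as_tibble(reads)
  samples <- as_tibble(samples)
  stopifnot(all(c("read_id", "sample", "seq") %in% names(reads)))
  stopifnot(all(c("sample", "individual", "timepoint") %in% names(samples)))
  if (anyDuplicated(reads$read_id) > 0) abort("duplicated read ids")
  unknown <- setdiff(reads$sample, samples$sample)
  if (length(unknown) > 0) {
    abort(paste0(
      "reads reference unknown sample(s): ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(unlist(strsplit(reads$seq, "", fixed = TRUE))), ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("invalid residue(s) in reads: ", paste(bad, collapse = ", ")))
  }
  widths <- unique(nchar(reads$seq))
  if (length(widths) > 1 && !allow_ragged) {
    abort("ragged alignment: sequences differ in length (trim first)")
  }
  structure(
    list(
      reads = reads,
      samples = samples,
      width = if (length(widths) == 1) widths else NA_integer_
    ),
    class = "aligned_reads",
    n_removed_short = 0L
  )
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(
    "<aligned_reads> ", nrow(x$reads), " reads, ",
    nrow(x$samples), " samples, width ", x$width, "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of reads in an aligned read set
#' @param x An `aligned_reads` object.
#' @return Integer count.
#' @export
n_reads <- function(x) nrow(x$reads)

read_sample_map_tsv <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("read_id", "sample", "individual", "timepoint")
  if (!all(need %in% names(map))) {
    abort(paste0(
      "sample map must have columns: ", paste(need, collapse = ", ")
    ))
  }
  map
}

#' Read an aligned FASTA plus its sample map
#'
#' The sample map is a four-column TSV (`read_id`, `sample`, `individual`,
#' `timepoint`). Every FASTA record must appear in the map.
#'
#' @param fasta_path Path to the (gapped) FASTA alignment.
#' @param sample_map_path Path to the TSV sample map.
#' @param allow_ragged Permit unequal read lengths (pre-trimming input).
#' @return An [aligned_reads()] object.
#' @export
read_aligned_fasta <- function(fasta_path, sample_map_path,
                               allow_ragged = FALSE) {
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("[ \t].*$", "", names(ss))
  map <- read_sample_map_tsv(sample_map_path)
  unmapped <- setdiff(ids, map$read_id)
  if (length(unmapped) > 0) {
    abort(paste0(
      "read(s) absent from sample map: ",
      paste(head(unmapped, 5), collapse = ", ")
    ))
  }
  reads <- tibble(read_id = ids, seq = unname(toupper(as.character(ss)))) |>
    left_join(map[c("read_id", "sample")], by = "read_id") |>
    select("read_id", "sample", "seq")
  samples <- distinct(map[c("sample", "individual", "timepoint")])
  aligned_reads(reads, samples, allow_ragged = allow_ragged)
}

#' Write an aligned read set to FASTA (and optionally its sample map)
#'
#' @param x An `aligned_reads` object.
#' @param fasta_path Output FASTA path.
#' @param sample_map_path Optional output TSV path for the sample map.
#' @return `x`, invisibly.
#' @export
write_aligned_fasta <- function(x, fasta_path, sample_map_path = NULL) {
  ss <- Biostrings::BStringSet(setNames(x$reads$seq, x$reads$read_id))
  Biostrings::writeXStringSet(ss, fasta_path)
  if (!is.null(sample_map_path)) {
    map <- left_join(x$reads[c("read_id", "sample")], x$samples, by = "sample")
    readr::write_tsv(map, sample_map_path)
  }
  invisible(x)
}

#' Trim reads to a fixed length, dropping shorter reads
#'
#' Keeps the first `length` characters of each read (5' anchor) and removes
#' reads shorter than `length`; the number removed is recorded in the
#' `n_removed_short` attribute.
#'
#' @param x An `aligned_reads` object (may be ragged).
#' @param length Target length in alignment columns (default 336 nt).
#' @return A rectangular `aligned_reads` object.
#' @export
trim_to_length <- function(x, length = 336) {
  stopifnot(inherits(x, "aligned_reads"), length >= 1)
  keep <- nchar(x$reads$seq) >= length
  reads <- x$reads[keep, ]
  reads$seq <- substr(reads$seq, 1L, length)
  out <- aligned_reads(reads, x$samples)
  attr(out, "n_removed_short") <-
    sum(!keep) + (attr(x, "n_removed_short") %||% 0L)
  out
}

#' Remove alignment columns that are all gaps
#'
#' Columns in which every read carries `-` convey no information and are
#' deleted; all other columns keep their relative order.
#'
#' @param x A rectangular `aligned_reads` object.
#' @return An `aligned_reads` object of possibly smaller width.
#' @export
drop_gap_only_columns <- function(x) {
  stopifnot(inherits(x, "aligned_reads"))
  if (nrow(x$reads) == 0) return(x)
  useq <- unique(x$reads$seq)
  cm <- seq_char_matrix(useq)
  gap_only <- colSums(cm != "-") == 0
  if (!any(gap_only)) return(x)
  keep <- which(!gap_only)
  lookup <- vapply(
    useq,
    function(s) paste(substring(s, keep, keep), collapse = ""),
    character(1)
  )
  reads <- x$reads
  reads$seq <- unname(lookup[reads$seq])
  out <- aligned_reads(reads, x$samples)
  attr(out, "n_removed_short") <- attr(x, "n_removed_short") %||% 0L
  out
}

#' Read a lineage-annotated reference FASTA
#'
#' Headers carry the reference id followed by a tab (or space) and a
#' semicolon-delimited lineage (`k__...;p__...;...`). Used for best-hit
#' taxonomy assignment of oligotype representatives.
#'
#' @param path Path to the reference FASTA.
#' @return A tibble of class `reference_db` with columns `ref_id`, `seq`,
#'   `lineage` and one column per taxonomic rank.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("[ \t].*$", "", headers)
  lineage <- ifelse(
    grepl("[ \t]", headers),
    trimws(sub("^[^ \t]+[ \t]+", "", headers)),
    NA_character_
  )
  if (anyDuplicated(ids) > 0) {
    abort(paste0(
      "duplicated reference id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  if (any(is.na(lineage) | !nzchar(lineage))) {
    abort(paste0(
      "reference record(s) missing lineage: ",
      paste(head(ids[is.na(lineage) | !nzchar(lineage)], 5), collapse = ", ")
    ))
  }
  db <- bind_cols(
    tibble(
      ref_id = ids, seq = unname(toupper(as.character(ss))),
      lineage = lineage
    ),
    parse_lineage(lineage)
  )
  if (any(!nzchar(db$seq))) abort("empty reference sequence")
  structure(db, class = c("reference_db", class(db)))
}

#' Write a lineage-annotated reference FASTA
#'
#' @param db A `reference_db` tibble (needs `ref_id`, `seq`, `lineage`).
#' @param path Output path.
#' @return `db`, invisibly.
#' @export
write_reference <- function(db, path) {
  ss <- Biostrings::BStringSet(
    setNames(db$seq, paste(db$ref_id, db$lineage, sep = "\t"))
  )
  Biostrings::writeXStringSet(ss, path)
  invisible(db)
}
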