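# Fixture builders shared across the test files. Everything is generated
# in code; no binary data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny aligned read set from parallel vectors
toy_reads <- function(seqs, samples = rep("S1", length(seqs)),
                      individuals = NULL, timepoints = NULL) {
  ids <- sprintf("r%03d", seq_along(seqs))
  smp <- sort(unique(samples))
  aligned_reads(
    tibble::tibble(read_id = ids, sample = samples, seq = seqs),
    tibble::tibble(
      sample = smp,
      individual = individuals %||% rep("I1", length(smp)),
      timepoint = timepoints %||% paste0("T", seq_along(smp))
    )
  )
}

# a rectangular read pool: n copies each of the given sequences
toy_pool <- function(...) {
  spec <- list(...)
  seqs <- unlist(lapply(spec, function(p) rep(p$seq, p$n)))
  toy_reads(seqs)
}

# an abundance table straight from a samples x taxa matrix
toy_abund <- function(m, level = "genus", individuals = NULL) {
  meta <- tibble::tibble(
    sample = rownames(m),
    individual = individuals %||% rownames(m),
    timepoint = paste0("T", seq_len(nrow(m)))
  )
  abund_from_matrix(m, level = level, meta = meta)
}

# per-individual two-point series realizing a given mean and CV exactly
# (sample SD of (m - d, m + d) is d * sqrt(2), so d = s / sqrt(2))
series_from_mean_cv <- function(stats_tbl) {
  rows <- lapply(seq_len(nrow(stats_tbl)), function(i) {
    m <- stats_tbl$mean[i] / 100
    s <- m * stats_tbl$cv[i] / 100
    d <- s / sqrt(2)
    tibble::tibble(
      individual = stats_tbl$individual[i],
      taxon = stats_tbl$taxon[i],
      sample = paste0(stats_tbl$individual[i], c("_T1", "_T2")),
      abundance = c(m - d, m + d)
    )
  })
  dplyr::bind_rows(rows)
}

# small end-to-end simulation used by several files
small_sim <- function(seed = 11, epsilon = 0, reads = 1500, ...) {
  args <- list(
    n_individuals = 2, n_timepoints = 2, n_genera = 2,
    oligos_per_genus = 3, reads_per_sample_mean = reads,
    reads_per_sample_sd = reads / 20, profile_sparsity = 5,
    fluctuation_alpha = 1e5, genus_alpha = 50,
    base_error_rate = epsilon, seed = seed
  )
  args <- utils::modifyList(args, list(...))
  simulate_community(do.call(synthetic_config, args))
}
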