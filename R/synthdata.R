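# Synthetic community generator. Emulates the statistical structure the
# downstream analysis assumes: a genus framework shared across individuals
# (same genera, individually differing proportions), sparse
# individual-specific oligotype profiles within each genus (the
# "fingerprint"), Dirichlet-multinomial fluctuation of per-sample
# composition around each individual's stable mean, and i.i.d. per-base
# substitution error on post-alignment reads. Emits full ground truth so
# recovery can be checked exactly.

#' Synthetic community configuration
#'
#' Defaults emulate an eight-individual, eight-timepoint supragingival
#' plaque sampling design with roughly 5618 reads per sample (SD 923.8) of
#' 336-nt aligned V4-V5 amplicons.
#'
#' @param n_individuals Number of subjects (default 8).
#' @param n_timepoints Number of timepoints per subject (default 8).
#' @param read_length Alignment width in nt (default 336).
#' @param n_genera Number of genera (default 10).
#' @param oligos_per_genus Oligotypes per genus; recycled to `n_genera`
#'   (default 12; the most diverse genus in the motivating data has 24).
#' @param reads_per_sample_mean,reads_per_sample_sd Normal parameters for
#'   per-sample read depth, truncated at 1 and rounded (defaults 5618 and
#'   923.8).
#' @param profile_sparsity Dirichlet concentration (< 1 for sparsity) of
#'   each individual's within-genus oligotype profile (default 0.1: a
#'   handful of oligotypes dominate per individual).
#' @param fluctuation_alpha Dirichlet precision of per-sample fluctuation
#'   around the individual mean profile; larger is more stable (default
#'   100, putting the temporal CV of an abundant oligotype near the tens of
#'   percent).
#' @param genus_alpha Dirichlet precision of per-individual genus means
#'   around the common base composition (default 25: individuals share the
#'   genus framework but in consistently differing proportions).
#' @param base_error_rate Per-base substitution probability (default 0.001).
#' @param seed Integer seed; stage seeds derive from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 8, n_timepoints = 8,
                             read_length = 336, n_genera = 10,
                             oligos_per_genus = 12,
                             reads_per_sample_mean = 5618,
                             reads_per_sample_sd = 923.8,
                             profile_sparsity = 0.1,
                             fluctuation_alpha = 100,
                             genus_alpha = 25,
                             base_error_rate = 0.001,
                             seed = 1) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_timepoints = as.integer(n_timepoints),
    read_length = as.integer(read_length),
    n_genera = as.integer(n_genera),
    oligos_per_genus = as.integer(rep_len(oligos_per_genus, n_genera)),
    reads_per_sample_mean = reads_per_sample_mean,
    reads_per_sample_sd = reads_per_sample_sd,
    profile_sparsity = profile_sparsity,
    fluctuation_alpha = fluctuation_alpha,
    genus_alpha = genus_alpha,
    base_error_rate = base_error_rate,
    seed = as.integer(seed)
  )
  counts <- c(
    cfg$n_individuals, cfg$n_timepoints, cfg$read_length, cfg$n_genera,
    cfg$oligos_per_genus
  )
  if (any(counts < 1)) abort("all counts must be >= 1")
  if (any(cfg$oligos_per_genus > cfg$read_length)) {
    abort("oligos_per_genus exceeds read_length: cannot plant distinct variants")
  }
  if (cfg$base_error_rate < 0 || cfg$base_error_rate >= 0.25) {
    abort("base_error_rate must lie in [0, 0.25)")
  }
  if (cfg$fluctuation_alpha <= 0) abort("fluctuation_alpha must be > 0")
  if (cfg$profile_sparsity <= 0) abort("profile_sparsity must be > 0")
  if (cfg$genus_alpha <= 0) abort("genus_alpha must be > 0")
  if (cfg$reads_per_sample_mean <= 0) abort("reads_per_sample_mean must be > 0")
  if (cfg$reads_per_sample_sd < 0) abort("reads_per_sample_sd must be >= 0")
  structure(cfg, class = "synthetic_config")
}

BASES <- c("A", "C", "G", "T")

#' Generate the planted oligotype library
#'
#' Per genus: one random root sequence plus K-1 variants, each obtained by
#' substituting the root at its own distinct alignment column, so every
#' pair of planted sequences differs at one or more columns and
#' within-genus identity stays high. Each oligotype gets a seven-rank
#' lineage (phyla cycle; the last fifth of a genus's oligotypes form a
#' second species, mirroring the major/minor species split seen within
#' plaque genera).
#'
#' @param config A [synthetic_config()].
#' @param seed Seed for this stage (default `config$seed`).
#' @return Object of class `ground_truth` with `$oligos` (tibble: oligo_id,
#'   genus, species, phylum, lineage, seq) and `$config`.
#' @export
generate_oligotype_library <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  L <- config$read_length
  rows <- purrr::map_dfr(seq_len(config$n_genera), function(g) {
    K <- config$oligos_per_genus[g]
    genus <- sprintf("Genus%02d", g)
    phylum <- sprintf("Phylum%02d", (g - 1) %% 4 + 1)
    root <- sample(BASES, L, replace = TRUE)
    var_cols <- if (K > 1) sample.int(L, K - 1) else integer()
    seqs <- character(K)
    seqs[1] <- paste(root, collapse = "")
    for (k in seq_len(K - 1)) {
      v <- root
      v[var_cols[k]] <- sample(setdiff(BASES, root[var_cols[k]]), 1)
      seqs[k + 1] <- paste(v, collapse = "")
    }
    n_sp1 <- if (K == 1) 1L else as.integer(ceiling(0.8 * K))
    species <- paste0(genus, "_sp", ifelse(seq_len(K) <= n_sp1, 1L, 2L))
    lineages <- vapply(seq_len(K), function(k) {
      make_lineage(
        "Bacteria", phylum, paste0(phylum, "_c"), paste0(phylum, "_o"),
        paste0(genus, "_f"), genus, species[k]
      )
    }, character(1))
    tibble(
      oligo_id = sprintf("%s_%02d", genus, seq_len(K)),
      genus = genus, species = species, phylum = phylum,
      lineage = lineages,
      seq = seqs
    )
  })
  stopifnot(anyDuplicated(rows$seq) == 0)
  structure(list(oligos = rows, config = config), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(
    "<ground_truth> ", nrow(x$oligos), " oligotypes in ",
    length(unique(x$oligos$genus)), " genera",
    if (!is.null(x$profiles)) {
      paste0("; ", length(unique(x$profiles$individual)), " individuals")
    } else "",
    if (!is.null(x$sample_info)) {
      paste0("; ", nrow(x$sample_info), " samples")
    } else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Generate per-individual mean community profiles
#'
#' Each individual's genus-level mean proportions are drawn once from a
#' Dirichlet around a common decreasing base composition (precision
#' `genus_alpha`), and, within each genus, a sparse oligotype profile is
#' drawn from a symmetric Dirichlet with concentration `profile_sparsity`.
#' The product gives the individual's fixed mean oligotype proportions:
#' stable means, individual-specific fingerprints.
#'
#' @param config A [synthetic_config()].
#' @param truth A [generate_oligotype_library()] result.
#' @param seed Seed for this stage (default `config$seed + 1`).
#' @return `truth` with `$genus_profiles` (individual, genus, mean_prop)
#'   and `$profiles` (individual, oligo_id, mean_prop) added.
#' @export
generate_individual_profiles <- function(config, truth,
                                         seed = config$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  G <- config$n_genera
  inds <- LETTERS[seq_len(config$n_individuals)]
  base <- 0.85^(seq_len(G) - 1)
  base <- base / sum(base)
  genus_names <- sprintf("Genus%02d", seq_len(G))
  genus_means <- rdirichlet(length(inds), config$genus_alpha * base)
  profiles <- purrr::map_dfr(seq_along(inds), function(i) {
    purrr::map_dfr(seq_len(G), function(g) {
      members <- truth$oligos$oligo_id[truth$oligos$genus == genus_names[g]]
      within <- as.vector(rdirichlet(
        1, rep(config$profile_sparsity, length(members))
      ))
      tibble(
        individual = inds[i],
        genus = genus_names[g],
        oligo_id = members,
        within_genus = within,
        mean_prop = genus_means[i, g] * within
      )
    })
  })
  truth$genus_profiles <- tibble(
    individual = rep(inds, each = G),
    genus = rep(genus_names, times = length(inds)),
    mean_prop = as.vector(t(genus_means))
  )
  truth$profiles <- profiles[c("individual", "oligo_id", "within_genus", "mean_prop")]
  truth
}

#' Draw per-sample read depths
#'
#' Normal draws rounded to integers and truncated at 1.
#'
#' @param n Number of samples.
#' @param mean,sd Normal parameters (defaults 5618 and 923.8).
#' @return Integer vector of length `n`.
#' @export
draw_sample_depths <- function(n, mean = 5618, sd = 923.8) {
  pmax(1L, as.integer(round(rnorm(n, mean, sd))))
}

default_timepoints <- function(n) {
  if (n == 8) c("D00", "D01", "D03", "W1", "W2", "W3", "M1", "M3")
  else sprintf("T%02d", seq_len(n))
}

mutate_reads <- function(seqs, epsilon) {
  if (epsilon == 0 || length(seqs) == 0) return(seqs)
  cm <- seq_char_matrix(seqs)
  eligible <- cm != "-" # reads are post-alignment; only bases mutate
  hits <- which(eligible & matrix(
    runif(length(cm)) < epsilon,
    nrow(cm), ncol(cm)
  ))
  if (length(hits) > 0) {
    cur <- cm[hits]
    repl <- vapply(cur, function(b) sample(setdiff(BASES, b), 1), character(1))
    cm[hits] <- repl
  }
  apply(cm, 1, paste, collapse = "")
}

#' Generate the time-series read set
#'
#' Per sample: realized oligotype proportions are drawn from a Dirichlet
#' with precision `fluctuation_alpha` around the individual's mean profile,
#' the read depth from the truncated normal, read counts multinomially, and
#' each non-gap base of each read is substituted independently with
#' probability `base_error_rate`.
#'
#' @param config A [synthetic_config()].
#' @param truth A [generate_individual_profiles()] result.
#' @param seed Seed for this stage (default `config$seed + 2`).
#' @param emit_reads Materialize read sequences (default `TRUE`). With
#'   `FALSE` only the per-sample proportions, depths and multinomial
#'   counts are drawn (sufficient for table-level studies) and `reads` is
#'   `NULL`.
#' @return List with `reads` (an [aligned_reads()] object) and `truth`
#'   augmented with `$sample_info` (sample, individual, timepoint,
#'   n_reads), `$sample_proportions` (realized Dirichlet proportions) and
#'   `$sample_counts` (realized multinomial read counts).
#' @export
generate_timeseries_reads <- function(config, truth,
                                      seed = config$seed + 2L,
                                      emit_reads = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), !is.null(truth$profiles))
  set.seed(seed)
  inds <- LETTERS[seq_len(config$n_individuals)]
  tps <- default_timepoints(config$n_timepoints)
  oligo_ids <- truth$oligos$oligo_id
  seq_of <- setNames(truth$oligos$seq, oligo_ids)
  samples <- tibble(
    sample = as.vector(outer(tps, inds, function(t, i) paste0(i, "_", t))),
    individual = rep(inds, each = length(tps)),
    timepoint = rep(tps, times = length(inds))
  )
  depths <- draw_sample_depths(
    nrow(samples), config$reads_per_sample_mean, config$reads_per_sample_sd
  )
  prof <- truth$profiles
  prop_rows <- vector("list", nrow(samples))
  count_rows <- vector("list", nrow(samples))
  read_rows <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    ind <- samples$individual[s]
    ind_prof <- prof[prof$individual == ind, ]
    mu <- ind_prof$mean_prop[match(oligo_ids, ind_prof$oligo_id)]
    alpha <- config$fluctuation_alpha * mu
    alpha <- pmax(alpha, 1e-12)
    props <- as.vector(rdirichlet(1, alpha))
    counts <- as.vector(rmultinom(1, depths[s], props))
    prop_rows[[s]] <- tibble(
      sample = samples$sample[s], oligo_id = oligo_ids, proportion = props
    )
    count_rows[[s]] <- tibble(
      sample = samples$sample[s], oligo_id = oligo_ids, count = counts
    )
    if (emit_reads) {
      seqs <- rep(seq_of, counts)
      seqs <- mutate_reads(unname(seqs), config$base_error_rate)
      read_rows[[s]] <- tibble(
        read_id = sprintf(
          "%s:%s:%s:%05d",
          samples$sample[s], ind, samples$timepoint[s], seq_along(seqs)
        ),
        sample = samples$sample[s],
        seq = seqs
      )
    }
  }
  truth$sample_info <- mutate(samples, n_reads = depths)
  truth$sample_proportions <- bind_rows(prop_rows)
  truth$sample_counts <- bind_rows(count_rows)
  reads <- if (emit_reads) aligned_reads(bind_rows(read_rows), samples) else NULL
  list(reads = reads, truth = truth)
}

#' Run the full synthetic generator
#'
#' Chains [generate_oligotype_library()], [generate_individual_profiles()]
#' and [generate_timeseries_reads()].
#'
#' @param config A [synthetic_config()].
#' @return List with `reads` and `truth`.
#' @export
simulate_community <- function(config) {
  truth <- generate_oligotype_library(config)
  truth <- generate_individual_profiles(config, truth)
  generate_timeseries_reads(config, truth)
}

#' Ground-truth abundance table
#'
#' Builds an abundance table directly from the generator's realized
#' per-sample proportions (or multinomial counts), optionally collapsed to
#' genus/species/phylum using the planted taxonomy. Used for recovery
#' oracles and resolution comparisons without re-running the decomposition.
#'
#' @param truth A `ground_truth` with sample-level draws.
#' @param level One of oligotype, species, genus, phylum.
#' @param source `"proportions"` (realized Dirichlet draws) or `"counts"`
#'   (realized reads).
#' @return An [abund_table()].
#' @export
truth_abundance_table <- function(truth,
                                  level = c("oligotype", "species", "genus", "phylum"),
                                  source = c("proportions", "counts")) {
  level <- match.arg(level)
  source <- match.arg(source)
  stopifnot(!is.null(truth$sample_proportions))
  base <- if (source == "proportions") {
    rename(truth$sample_proportions, abundance = "proportion")
  } else {
    tot <- truth$sample_counts |>
      group_by(.data$sample) |>
      mutate(abundance = .data$count / sum(.data$count)) |>
      ungroup()
    tot[c("sample", "oligo_id", "abundance")]
  }
  key <- if (level == "oligotype") "oligo_id" else level
  base <- base |>
    left_join(truth$oligos[c("oligo_id", "genus", "species", "phylum")],
      by = "oligo_id"
    ) |>
    group_by(sample = .data$sample, taxon = .data[[key]]) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    left_join(truth$sample_info[c("sample", "individual", "timepoint")],
      by = "sample"
    )
  abund_table(base, level = level)
}

#' Write the synthetic bundle to disk
#'
#' Emits the aligned FASTA, the four-column sample map, a reference FASTA
#' with tab-separated lineage headers (the planted library doubling as the
#' taxonomy reference), and ground-truth TSVs.
#'
#' @param sim A [simulate_community()] result.
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "reads.fasta"),
    sample_map = file.path(dir, "sample_map.tsv"),
    reference = file.path(dir, "reference.fasta"),
    profiles = file.path(dir, "truth_profiles.tsv"),
    sample_proportions = file.path(dir, "truth_sample_proportions.tsv"),
    sample_info = file.path(dir, "truth_sample_info.tsv")
  )
  write_aligned_fasta(sim$reads, paths[["fasta"]], paths[["sample_map"]])
  ref <- sim$truth$oligos |>
    transmute(
      ref_id = .data$oligo_id, seq = gsub("-", "", .data$seq, fixed = TRUE),
      lineage = .data$lineage
    )
  write_reference(ref, paths[["reference"]])
  readr::write_tsv(sim$truth$profiles, paths[["profiles"]])
  readr::write_tsv(sim$truth$sample_proportions, paths[["sample_proportions"]])
  readr::write_tsv(sim$truth$sample_info, paths[["sample_info"]])
  invisible(paths)
}
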