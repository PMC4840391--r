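# End-to-end orchestration: config validation, stage sequencing
# (cleanup -> decomposition -> taxonomy -> tables -> stability ->
# ordination), artifact writing, and a machine-readable run report.

config_defaults <- function() {
  list(
    M = 60, V = 3, m = 0.0965,
    genus_filter = 0.01, abundant_threshold = 0.10, otu_identity = 0.97,
    trim_length = 336,
    n_starts = 20, n_trials = 50,
    out_dir = NULL, seed = 1
  )
}

#' Build and validate a pipeline run configuration
#'
#' Exactly one input mode must be given: real (paths to an aligned FASTA,
#' a sample map and a lineage-annotated reference) or synthetic (a
#' [synthetic_config()] or a list of its arguments).
#'
#' @param fasta,sample_map,reference Input paths (real mode).
#' @param synthetic A [synthetic_config()] or argument list (synthetic
#'   mode).
#' @param ... Overrides of the defaults: `M` (60), `V` (3), `m` (0.0965),
#'   `genus_filter` (0.01), `abundant_threshold` (0.10), `otu_identity`
#'   (0.97), `trim_length` (336), `n_starts` (20), `n_trials` (50),
#'   `out_dir`, `seed` (1).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(fasta = NULL, sample_map = NULL, reference = NULL,
                       synthetic = NULL, ...) {
  dots <- list(...)
  defaults <- config_defaults()
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, dots)
  real <- !is.null(fasta) || !is.null(sample_map) || !is.null(reference)
  if (real && !is.null(synthetic)) {
    abort("give either input paths or a synthetic config, not both")
  }
  if (!real && is.null(synthetic)) {
    abort("one of input paths or a synthetic config is required")
  }
  if (real) {
    missing_paths <- c(
      if (is.null(fasta)) "fasta",
      if (is.null(sample_map)) "sample_map",
      if (is.null(reference)) "reference"
    )
    if (length(missing_paths) > 0) {
      abort(paste0(
        "real mode needs all input paths; missing: ",
        paste(missing_paths, collapse = ", ")
      ))
    }
    cfg$mode <- "real"
    cfg$fasta <- fasta
    cfg$sample_map <- sample_map
    cfg$reference <- reference
  } else {
    cfg$mode <- "synthetic"
    cfg$synthetic <- if (inherits(synthetic, "synthetic_config")) {
      synthetic
    } else {
      do.call(synthetic_config, as.list(synthetic))
    }
  }
  bad <- character()
  if (cfg$M < 1) bad <- c(bad, "M must be >= 1")
  if (cfg$V < 0) bad <- c(bad, "V must be >= 0")
  if (cfg$m < 0) bad <- c(bad, "m must be >= 0")
  for (key in c("genus_filter", "abundant_threshold", "otu_identity")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      bad <- c(bad, paste0(key, " must lie in (0, 1)"))
    }
  }
  if (cfg$n_starts < 1 || cfg$n_trials < 1) {
    bad <- c(bad, "n_starts and n_trials must be >= 1")
  }
  if (length(bad) > 0) {
    abort(paste0("invalid config: ", paste(bad, collapse = "; ")))
  }
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [run_config()] arguments; a `synthetic:` block
#' holds [synthetic_config()] arguments. Unknown keys or out-of-range
#' values are validation errors.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path) %||% list()
  known <- c(
    names(config_defaults()), "fasta", "sample_map", "reference", "synthetic"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), names(config_defaults()))]
  do.call(run_config, c(
    list(
      fasta = raw$fasta, sample_map = raw$sample_map,
      reference = raw$reference,
      synthetic = raw$synthetic %||% (
        if (is.null(raw$fasta)) list() else NULL
      )
    ),
    args
  ))
}

#' Run the full analysis pipeline
#'
#' Executes input acquisition (or synthesis), cleanup (fixed-length
#' trimming, gap-only column removal), entropy decomposition, taxonomy
#' assignment, multi-level abundance tables (phylum, genus, species, 97%
#' OTU, oligotype), genus- and oligotype-level stability statistics, the
#' fingerprint summary, NMDS ordination at genus and oligotype level, the
#' topology-consistency check, and leave-one-out individual
#' identification. All artifacts are written under `config$out_dir` (TSV /
#' FASTA / JSON) along with a MANIFEST; a run report list is returned.
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly contains table objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir %||% tempfile("oligostab_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  stage <- "setup"
  note_artifact <- function(path) manifest <<- c(manifest, path)
  finish_manifest <- function(status) {
    writeLines(
      c(paste0("status: ", status), manifest),
      file.path(out_dir, "MANIFEST")
    )
  }
  report <- list(seed = config$seed, mode = config$mode, out_dir = out_dir)
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      finish_manifest(paste0("incomplete (failed at stage ", stage, ")"))
      abort(paste0("pipeline failed at stage '", stage, "': ",
                   conditionMessage(e)))
    })
  }

  # --- input -----------------------------------------------------------
  truth <- NULL
  inputs <- run_stage("input", {
    if (config$mode == "synthetic") {
      sim <- simulate_community(config$synthetic)
      truth <- sim$truth # assigns in the run_pipeline frame (promise env)
      bundle <- write_synthetic_bundle(sim, file.path(out_dir, "input"))
      note_artifact(unname(bundle))
      list(reads = sim$reads, refdb = read_reference(bundle[["reference"]]))
    } else {
      list(
        reads = read_aligned_fasta(config$fasta, config$sample_map,
          allow_ragged = TRUE
        ),
        refdb = read_reference(config$reference)
      )
    }
  })

  # --- cleanup ---------------------------------------------------------
  reads <- run_stage("cleanup", {
    r <- trim_to_length(inputs$reads, config$trim_length)
    drop_gap_only_columns(r)
  })
  report$n_reads_in <- n_reads(reads)
  report$n_removed_short <- attr(reads, "n_removed_short")

  # --- decomposition ---------------------------------------------------
  med <- run_stage("decompose", {
    med_decompose(reads, M = config$M, V = config$V, m = config$m)
  })
  note_artifact(write_med_result(med, file.path(out_dir, "decompose")))
  report$accounting <- med$accounting
  report$n_oligotypes <- nrow(med$nodes)

  # --- taxonomy --------------------------------------------------------
  taxa <- run_stage("taxonomy", assign_taxonomy(med, inputs$refdb))
  tax_path <- file.path(out_dir, "assignments.tsv")
  readr::write_tsv(
    taxa[c("node_id", "lineage", "percent_identity", "n_best_hits")],
    tax_path
  )
  note_artifact(tax_path)

  # --- community tables ------------------------------------------------
  meta <- reads$samples
  tables <- run_stage("tables", {
    otu_map <- bin_otus_97(med, threshold = config$otu_identity)
    tabs <- list(
      oligotype = to_relative(
        collapse_counts(med$counts, taxa, "oligotype"), "oligotype", meta
      ),
      species = to_relative(
        collapse_counts(med$counts, taxa, "species"), "species", meta
      ),
      genus = to_relative(
        collapse_counts(med$counts, taxa, "genus"), "genus", meta
      ),
      phylum = to_relative(
        collapse_counts(med$counts, taxa, "phylum"), "phylum", meta
      ),
      otu97 = to_relative(collapse_otus(med$counts, otu_map), "otu97", meta)
    )
    attr(tabs, "otu_map") <- otu_map
    tabs
  })
  report$n_otus97 <- length(unique(attr(tables, "otu_map")$otu_id))
  tbl_dir <- file.path(out_dir, "tables")
  dir.create(tbl_dir, showWarnings = FALSE)
  report$table_paths <- vapply(names(tables), function(nm) {
    p <- file.path(tbl_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), p)
    note_artifact(p)
    p
  }, character(1))

  # --- stability -------------------------------------------------------
  stability <- run_stage("stability", {
    genus_tbl <- mean_abundance_filter(tables$genus, config$genus_filter)
    gstats <- per_individual_stats(genus_tbl)
    gagg <- aggregate_stats(gstats, genus_tbl)
    # fingerprint within the most abundant genus
    top_genus <- names(attr(genus_tbl, "taxon_means"))[1]
    prof <- within_genus_profile(tables$oligotype, top_genus, taxa)
    pstats <- per_individual_stats(prof)
    pagg <- aggregate_stats(pstats, prof)
    fp <- fingerprint_summary(
      pstats, pagg,
      threshold = 100 * config$abundant_threshold
    )
    anomalies <- anomaly_series(genus_tbl)
    list(
      genus_stats = gstats, genus_aggregates = gagg,
      genus_table = format_stability_table(gstats, gagg),
      profile_genus = top_genus,
      profile_stats = pstats, profile_aggregates = pagg,
      fingerprint = fp, anomalies = anomalies
    )
  })
  stab_dir <- file.path(out_dir, "stability")
  dir.create(stab_dir, showWarnings = FALSE)
  readr::write_tsv(stability$genus_table, file.path(stab_dir, "genus_stability.tsv"))
  readr::write_tsv(
    format_stability_table(stability$profile_stats, stability$profile_aggregates),
    file.path(stab_dir, "oligotype_profile_stability.tsv")
  )
  readr::write_tsv(stability$anomalies, file.path(stab_dir, "anomalies.tsv"))
  note_artifact(file.path(stab_dir, c(
    "genus_stability.tsv", "oligotype_profile_stability.tsv", "anomalies.tsv"
  )))
  report$fingerprint <- as.list(stability$fingerprint)
  report$profile_genus <- stability$profile_genus

  # --- ordination ------------------------------------------------------
  ordi <- run_stage("ordination", {
    fits <- lapply(tables[c("genus", "oligotype")], function(t) {
      nmds(bray_curtis(t),
        n_starts = config$n_starts, seed = stage_seeds[1],
        meta = sample_meta(t)
      )
    })
    topo <- topology_consistency(
      bray_curtis(tables$oligotype),
      n_trials = config$n_trials, seed = stage_seeds[2]
    )
    loo <- lapply(
      tables[c("genus", "oligotype")],
      function(t) fingerprint_loo(t)$accuracy
    )
    list(fits = fits, topo = topo, loo = loo)
  })
  ord_dir <- file.path(out_dir, "ordination")
  dir.create(ord_dir, showWarnings = FALSE)
  for (nm in names(ordi$fits)) {
    p <- file.path(ord_dir, paste0(nm, "_coordinates.tsv"))
    readr::write_tsv(ordi$fits[[nm]]$points, p)
    note_artifact(p)
  }
  report$stress <- lapply(ordi$fits, function(f) f$stress)
  report$topology <- list(
    n_consistent = ordi$topo$n_consistent, n_trials = ordi$topo$n_trials
  )
  report$loo_accuracy <- ordi$loo

  # --- recovery check (synthetic mode) --------------------------------
  if (!is.null(truth)) {
    report$n_planted <- nrow(truth$oligos)
    report$n_recovered_exact <- sum(
      med$nodes$representative %in% truth$oligos$seq
    )
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    report[setdiff(names(report), "table_paths")],
    report_path,
    auto_unbox = TRUE, digits = NA
  )
  note_artifact(report_path)
  finish_manifest("complete")
  structure(
    c(report, list(tables = tables, med = med, stability = stability,
                   ordination = ordi)),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  reads in:      ", x$accounting$n_input, "\n")
  cat("  retained:      ", x$accounting$n_retained, "\n")
  cat("  oligotypes:    ", x$n_oligotypes, "\n")
  cat("  97% OTUs:      ", x$n_otus97, "\n")
  cat(
    "  stress (oligo):", signif(x$stress$oligotype, 3),
    " topology ", x$topology$n_consistent, "/", x$topology$n_trials, "\n"
  )
  cat(
    "  LOO accuracy:   genus ", signif(x$loo_accuracy$genus, 3),
    ", oligotype ", signif(x$loo_accuracy$oligotype, 3), "\n"
  )
  invisible(x)
}
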