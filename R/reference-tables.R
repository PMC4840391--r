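# Published summary statistics shipped as plain-text fixtures: printed
# per-individual mean/CV tables from a three-month supragingival plaque
# time series of eight adults (eight samples each), at the genus level and
# for the oligotypes of its most abundant genus (Corynebacterium). They
# anchor the package's aggregation conventions (sample SD, unweighted
# cross-individual means) to printed values.

#' Published plaque stability reference tables
#'
#' Loads the bundled printed summary tables: per-individual mean relative
#' abundance (percent) and CV (percent) for the ten most abundant plaque
#' genera, or for the Corynebacterium oligotypes, plus the printed overall
#' (all-samples) aggregates. Cells absent from the printed oligotype table
#' (oligotype undetected in an individual) are simply missing rows.
#'
#' @param which `"genus"` or `"corynebacterium"`.
#' @return List with `stats` (tibble: taxon, individual, mean, cv) and
#'   `overall` (tibble: taxon, overall_mean, overall_cv, and for the genus
#'   table mean_cv).
#' @export
plaque_reference_stats <- function(which = c("genus", "corynebacterium")) {
  which <- match.arg(which)
  stem <- if (which == "genus") "plaque_genus" else "plaque_cory"
  stats_file <- if (which == "genus") {
    "plaque_genus_stability.tsv"
  } else {
    "plaque_cory_oligotype_stability.tsv"
  }
  read <- function(f) {
    readr::read_tsv(
      system.file("extdata", f, package = "oligostab", mustWork = TRUE),
      show_col_types = FALSE
    )
  }
  list(
    stats = read(stats_file),
    overall = read(paste0(stem, "_overall.tsv"))
  )
}
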