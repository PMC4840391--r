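# broom-style tidiers for the fitted objects.

#' Tidy a decomposition result
#'
#' One row per oligotype node.
#'
#' @param x A `med_result`.
#' @param ... Unused.
#' @return Tibble: node_id, representative, n_reads, top_count,
#'   max_entropy.
#' @export
tidy.med_result <- function(x, ...) x$nodes

#' One-row summary of a decomposition
#'
#' @param x A `med_result`.
#' @param ... Unused.
#' @return Tibble with the read-accounting integers and parameters.
#' @export
glance.med_result <- function(x, ...) {
  a <- x$accounting
  tibble(
    n_input = a$n_input,
    n_retained = a$n_retained,
    n_removed_min_abundance = a$n_removed_min_abundance,
    n_removed_max_variation = a$n_removed_max_variation,
    n_nodes = nrow(x$nodes),
    M = x$params$M, V = x$params$V, m = x$params$m
  )
}

#' Tidy an NMDS fit
#'
#' @param x An `nmds_fit`.
#' @param ... Unused.
#' @return The points tibble (sample, MDS1, MDS2, metadata).
#' @export
tidy.nmds_fit <- function(x, ...) x$points

#' One-row summary of an NMDS fit
#'
#' @param x An `nmds_fit`.
#' @param ... Unused.
#' @return Tibble: stress, dims, n_starts, n_samples, converged.
#' @export
glance.nmds_fit <- function(x, ...) {
  tibble(
    stress = x$stress, dims = x$dims, n_starts = x$n_starts,
    n_samples = nrow(x$points), converged = x$converged
  )
}
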