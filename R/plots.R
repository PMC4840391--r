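# ggplot2 views of the result objects: ordination with covariance
# ellipses, anomaly-from-mean ribbons, and stacked abundance profiles.

#' Ordination scatter plot with per-group covariance ellipses
#'
#' @param fit An [nmds()] fit whose points carry a grouping column.
#' @param group_col Metadata column to color and ellipse by (default
#'   "individual").
#' @param ellipse Draw 1-SD covariance ellipses (default `TRUE`; needs >= 3
#'   points per group).
#' @param ellipse_radius SD multiplier for the ellipses.
#' @return A ggplot object.
#' @export
plot_ordination <- function(fit, group_col = "individual", ellipse = TRUE,
                            ellipse_radius = 1) {
  stopifnot(inherits(fit, "nmds_fit"))
  pts <- fit$points
  if (!group_col %in% names(pts)) {
    abort(paste0("no '", group_col, "' column in ordination points"))
  }
  p <- ggplot(pts, aes(.data$MDS1, .data$MDS2, colour = .data[[group_col]])) +
    geom_point(size = 2) +
    labs(
      x = "MDS1", y = "MDS2", colour = group_col,
      caption = paste0("stress = ", signif(fit$stress, 3))
    ) +
    theme_minimal()
  if (ellipse) {
    ell <- covariance_ellipse(fit, group_col = group_col)
    path <- ellipse_path(ell, radius = ellipse_radius)
    p <- p + geom_path(
      data = path,
      aes(.data$x, .data$y, colour = .data$group),
      inherit.aes = FALSE
    )
  }
  p
}

#' @export
autoplot.nmds_fit <- function(object, ...) plot_ordination(object, ...)

#' Anomaly-from-mean panel
#'
#' One panel per (taxon, individual): the anomaly series over timepoints
#' with the +-1 and +-2 SD bands around zero.
#'
#' @param anomalies An [anomaly_series()] tibble.
#' @param taxa Optional subset of taxa to show.
#' @return A ggplot object.
#' @export
plot_anomaly <- function(anomalies, taxa = NULL) {
  d <- anomalies
  if (!is.null(taxa)) d <- filter(d, .data$taxon %in% taxa)
  d <- mutate(d,
    t = match(.data$timepoint, unique(.data$timepoint)),
    band1 = .data$sd, band2 = 2 * .data$sd
  )
  ggplot(d, aes(.data$t, .data$anomaly)) +
    geom_ribbon(
      aes(ymin = -.data$band2, ymax = .data$band2),
      fill = "grey85"
    ) +
    geom_ribbon(
      aes(ymin = -.data$band1, ymax = .data$band1),
      fill = "grey70"
    ) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_grid(taxon ~ individual, scales = "free_y") +
    labs(x = "timepoint", y = "anomaly from individual mean") +
    theme_minimal()
}

#' Stacked abundance profile bars
#'
#' Per-sample stacked relative abundances, faceted by individual.
#'
#' @param x An `abund_tbl`.
#' @return A ggplot object.
#' @export
plot_profile_bars <- function(x) {
  d <- as_tibble(x)
  ggplot(d, aes(.data$sample, .data$abundance, fill = .data$taxon)) +
    geom_col(width = 0.9) +
    {
      if ("individual" %in% names(d)) {
        facet_grid(~individual, scales = "free_x", space = "free_x")
      }
    } +
    labs(x = NULL, y = "relative abundance", fill = abund_level(x)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}
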