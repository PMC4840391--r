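# Bray-Curtis dissimilarity, multi-start non-metric MDS (Kruskal stress-1),
# per-group covariance ellipses, and the repeated-random-start topology
# consistency check.

#' Bray-Curtis dissimilarity between samples
#'
#' BC(i, j) = sum |x_it - x_jt| / sum (x_it + x_jt) over taxa t. Rows need
#' not sum to one (shared-taxon-subset tables keep whole-community
#' fractions).
#'
#' @param x An `abund_tbl` (or sample/taxon/abundance tibble) or a numeric
#'   samples x taxa matrix.
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- if (is.matrix(x)) x else abund_matrix(x)
  if (any(m < 0)) abort("negative abundances")
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2) {
    abort(paste0(
      "Bray-Curtis undefined for all-zero sample pair(s): ",
      paste(head(rownames(m)[zero], 5), collapse = ", ")
    ))
  }
  vegan::vegdist(m, method = "bray")
}

#' Kruskal stress-1 of a configuration against dissimilarities
#'
#' Evaluates stress-1 by monotone (isotonic) regression of configuration
#' distances on the input dissimilarities: sqrt(sum (d_conf - d_hat)^2 /
#' sum d_conf^2). Used as an independent check of the fitted ordination and
#' for invariance tests.
#'
#' @param d A `dist` of input dissimilarities.
#' @param coords Numeric matrix of configuration coordinates (rows in the
#'   same order as `d`'s labels).
#' @return Stress-1 in `[0, 1]`.
#' @export
stress_kruskal <- function(d, coords) {
  dvec <- as.vector(d)
  conf <- as.vector(dist(coords))
  ord <- order(dvec)
  fit <- isoreg(dvec[ord], conf[ord])
  sqrt(sum((conf[ord] - fit$yf)^2) / sum(conf^2))
}

#' Non-metric multidimensional scaling with random restarts
#'
#' Minimizes Kruskal stress-1 (monotone regression, as in standard NMDS)
#' from multiple starting configurations: a metric-scaling start plus
#' `n_starts - 1` random starts. The best (lowest-stress) configuration is
#' returned, centered at the origin. Deterministic for a fixed `seed`.
#'
#' @param d A `dist` of dissimilarities.
#' @param dims Number of ordination dimensions (default 2).
#' @param n_starts Number of starting configurations (default 20).
#' @param max_iter Maximum iterations per start (default 500).
#' @param seed Optional integer seed.
#' @param meta Optional per-sample metadata tibble to join onto the points.
#' @return Object of class `nmds_fit`: `points` (tibble sample, MDS1,
#'   MDS2, ...), `stress`, `n_starts`, `dims`, `converged`.
#' @export
nmds <- function(d, dims = 2, n_starts = 20, max_iter = 500, seed = NULL,
                 meta = NULL) {
  n <- attr(d, "Size")
  if (is.null(n) || n < dims + 1) abort("need at least dims + 1 samples")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) {
      cmdscale(d, k = dims)
    } else {
      matrix(runif(n * dims, -1, 1), n, dims)
    }
    fit <- vegan::monoMDS(
      d, y = init, k = dims, model = "global", maxit = max_iter
    )
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  colnames(pts) <- paste0("MDS", seq_len(dims))
  labs <- attr(d, "Labels") %||% as.character(seq_len(n))
  points <- bind_cols(tibble(sample = labs), as_tibble(pts))
  if (!is.null(meta)) points <- left_join(points, as_tibble(meta), by = "sample")
  structure(
    list(
      points = points, stress = best$stress, n_starts = n_starts,
      dims = dims, converged = isTRUE(best$icause %in% 3:4) || best$stress < 1e-4
    ),
    class = "nmds_fit"
  )
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(
    "<nmds_fit> ", nrow(x$points), " samples, ", x$dims,
    " dims, stress ", signif(x$stress, 3),
    " (best of ", x$n_starts, " starts)\n",
    sep = ""
  )
  invisible(x)
}

#' Per-group covariance ellipses of ordination coordinates
#'
#' For each group: the mean point and the sample (n-1) covariance of the
#' 2-D coordinates, summarized as ellipse parameters (principal axes =
#' eigenvectors, half-widths = multiplier x sqrt(eigenvalues); 1 SD by
#' default).
#'
#' @param coords An `nmds_fit`, or a tibble/matrix with two coordinate
#'   columns.
#' @param group Group label per point (ignored when `coords` is an
#'   `nmds_fit` and `group_col` names a metadata column).
#' @param group_col Column of `nmds_fit$points` holding group labels
#'   (default "individual").
#' @return Tibble per group: n, mean_x, mean_y, var_x, var_y, cov_xy,
#'   half_major, half_minor, angle (radians), degenerate flag.
#' @export
covariance_ellipse <- function(coords, group = NULL, group_col = "individual") {
  if (inherits(coords, "nmds_fit")) {
    pts <- as.matrix(coords$points[c("MDS1", "MDS2")])
    group <- coords$points[[group_col]]
  } else if (is.matrix(coords)) {
    pts <- coords[, 1:2, drop = FALSE]
  } else {
    cc <- as_tibble(coords)
    num <- names(cc)[vapply(cc, is.numeric, logical(1))]
    pts <- as.matrix(cc[num[1:2]])
  }
  if (is.null(group)) abort("group labels required")
  counts <- table(group)
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    abort(paste0(
      "group(s) with fewer than 3 points: ", paste(small, collapse = ", ")
    ))
  }
  purrr::map_dfr(sort(unique(as.character(group))), function(g) {
    p <- pts[group == g, , drop = FALSE]
    mu <- colMeans(p)
    cv <- cov(p)
    eig <- eigen(cv, symmetric = TRUE)
    ev <- pmax(eig$values, 0)
    tibble(
      group = g, n = nrow(p),
      mean_x = mu[1], mean_y = mu[2],
      var_x = cv[1, 1], var_y = cv[2, 2], cov_xy = cv[1, 2],
      half_major = sqrt(ev[1]), half_minor = sqrt(ev[2]),
      angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
      degenerate = ev[2] < .Machine$double.eps * max(ev[1], 1)
    )
  })
}

#' Polygon path of a covariance ellipse
#'
#' @param ellipses A [covariance_ellipse()] tibble.
#' @param radius SD multiplier (default 1).
#' @param n Points per ellipse.
#' @return Tibble: group, x, y.
#' @export
ellipse_path <- function(ellipses, radius = 1, n = 100) {
  theta <- seq(0, 2 * pi, length.out = n)
  purrr::map_dfr(seq_len(nrow(ellipses)), function(i) {
    e <- ellipses[i, ]
    a <- radius * e$half_major
    b <- radius * e$half_minor
    rot <- matrix(
      c(cos(e$angle), sin(e$angle), -sin(e$angle), cos(e$angle)), 2, 2
    )
    xy <- cbind(a * cos(theta), b * sin(theta)) %*% t(rot)
    tibble(group = e$group, x = xy[, 1] + e$mean_x, y = xy[, 2] + e$mean_y)
  })
}

#' Procrustes correlation between two configurations
#'
#' Symmetric Procrustes superimposition (translation, rotation, reflection,
#' scaling); the correlation is sqrt(1 - ss).
#'
#' @param x,y Coordinate matrices with matching rows.
#' @return Correlation in `[0, 1]`.
#' @export
procrustes_cor <- function(x, y) {
  pr <- vegan::procrustes(as.matrix(x), as.matrix(y), symmetric = TRUE)
  sqrt(max(0, 1 - pr$ss))
}

#' Topology consistency of NMDS over repeated random starts
#'
#' Runs NMDS `n_trials` times from independent random starts, superimposes
#' each trial's configuration onto the lowest-stress one by Procrustes, and
#' counts a trial as consistent when its Procrustes correlation reaches the
#' threshold. Operationalizes the "topology consistent in k of n trials"
#' check.
#'
#' @param d A `dist` of dissimilarities.
#' @param n_trials Number of random-start trials (default 50).
#' @param seed Optional integer seed.
#' @param threshold Procrustes correlation for consistency (default 0.99).
#' @param starts_per_trial Random initializations per trial, best kept
#'   (default 3, so a trial reflects the stress landscape rather than a
#'   single unlucky start).
#' @param dims,max_iter Passed to the underlying NMDS.
#' @return List of class `topology_check`: `n_consistent`, `n_trials`,
#'   `correlations`, `stresses`.
#' @export
topology_consistency <- function(d, n_trials = 50, seed = NULL,
                                 threshold = 0.99, starts_per_trial = 3,
                                 dims = 2, max_iter = 500) {
  n <- attr(d, "Size")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(seq_len(n_trials), function(i) {
    best <- NULL
    for (s in seq_len(starts_per_trial)) {
      init <- matrix(runif(n * dims, -1, 1), n, dims)
      f <- vegan::monoMDS(d, y = init, k = dims, model = "global",
                          maxit = max_iter)
      if (is.null(best) || f$stress < best$stress) best <- f
    }
    best
  })
  stresses <- vapply(fits, function(f) f$stress, numeric(1))
  ref <- fits[[which.min(stresses)]]$points
  cors <- vapply(
    fits,
    function(f) procrustes_cor(ref, f$points),
    numeric(1)
  )
  structure(
    list(
      n_consistent = sum(cors >= threshold),
      n_trials = n_trials,
      correlations = cors,
      stresses = stresses
    ),
    class = "topology_check"
  )
}

#' @export
print.topology_check <- function(x, ...) {
  cat(
    "<topology_check> consistent in ", x$n_consistent, " of ",
    x$n_trials, " trials\n",
    sep = ""
  )
  invisible(x)
}
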