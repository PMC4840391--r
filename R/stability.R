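# Temporal stability statistics: per-individual mean/SD/CV per taxon,
# pooled overall statistics, anomaly-from-mean series, within-genus
# oligotype profiles, the abundant-oligotype fingerprint contrast, and a
# nearest-centroid individual-identification check.
#
# Conventions (pinned by forensic checks in the test suite): the sample
# standard deviation (n-1 denominator), CV% = 100*sd/mean undefined (NA)
# when the mean is exactly zero, means reported on the percent scale.

#' Per-individual mean, SD and CV for every taxon
#'
#' For each (individual, taxon) pair, computes the mean relative abundance,
#' its sample standard deviation (n-1 denominator) and the coefficient of
#' variation over that individual's time series. Absent (sample, taxon)
#' pairs count as zero abundance.
#'
#' @param x An `abund_tbl` of relative abundances (proportions) with an
#'   `individual` column.
#' @param percent_scale Report means/SDs on the percent scale (default);
#'   CV is scale-free.
#' @return A tibble of class `stability_tbl`: `individual`, `taxon`, `n`,
#'   `mean`, `sd`, `cv` (CV in percent, `NA` where the mean is zero).
#' @export
per_individual_stats <- function(x, percent_scale = TRUE) {
  if (!"individual" %in% names(x)) abort("abundance table lacks 'individual'")
  x <- complete_grid(x)
  n_by_ind <- count(sample_meta(x), .data$individual)
  too_few <- n_by_ind$individual[n_by_ind$n < 2]
  if (length(too_few) > 0) {
    abort(paste0(
      "individual(s) with fewer than 2 samples: ",
      paste(too_few, collapse = ", ")
    ))
  }
  scale <- if (percent_scale) 100 else 1
  out <- as_tibble(x) |>
    group_by(.data$individual, .data$taxon) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$abundance) * scale,
      sd = sd(.data$abundance) * scale,
      .groups = "drop"
    ) |>
    mutate(cv = ifelse(.data$mean == 0, NA_real_, 100 * .data$sd / .data$mean))
  structure(out, class = c("stability_tbl", class(out)))
}

#' Pooled overall and cross-individual aggregate statistics
#'
#' Per taxon: the mean, SD and CV pooled over all samples from all
#' individuals (`overall_*`), and the unweighted mean of the per-individual
#' CVs (`mean_cv`, defined entries only).
#'
#' @param stats A [per_individual_stats()] tibble.
#' @param x The same `abund_tbl` the stats were computed from.
#' @param percent_scale As in [per_individual_stats()].
#' @return Tibble: `taxon`, `n_individuals`, `overall_mean`, `overall_sd`,
#'   `overall_cv`, `mean_cv`.
#' @export
aggregate_stats <- function(stats, x, percent_scale = TRUE) {
  x <- complete_grid(x)
  scale <- if (percent_scale) 100 else 1
  pooled <- as_tibble(x) |>
    group_by(.data$taxon) |>
    summarise(
      overall_mean = mean(.data$abundance) * scale,
      overall_sd = sd(.data$abundance) * scale,
      .groups = "drop"
    ) |>
    mutate(overall_cv = ifelse(
      .data$overall_mean == 0, NA_real_,
      100 * .data$overall_sd / .data$overall_mean
    ))
  cvbar <- as_tibble(stats) |>
    group_by(.data$taxon) |>
    summarise(
      n_individuals = dplyr::n(),
      mean_cv = mean(.data$cv, na.rm = TRUE),
      .groups = "drop"
    )
  left_join(cvbar, pooled, by = "taxon") |>
    select(
      "taxon", "n_individuals", "overall_mean", "overall_sd",
      "overall_cv", "mean_cv"
    )
}

#' Format a printed-style stability table
#'
#' Rounds to report conventions (means to 1 decimal, CVs to the nearest
#' integer, half away from zero) and widens to one M/CV column pair per
#' individual plus the overall columns.
#'
#' @param stats A [per_individual_stats()] tibble.
#' @param aggregates An [aggregate_stats()] tibble.
#' @return A wide tibble, one row per taxon.
#' @export
format_stability_table <- function(stats, aggregates) {
  per_ind <- as_tibble(stats) |>
    transmute(
      taxon = .data$taxon, individual = .data$individual,
      M = round_half_up(.data$mean, 1),
      CV = round_half_up(.data$cv)
    ) |>
    tidyr::pivot_wider(
      names_from = "individual", values_from = c("M", "CV"),
      names_glue = "{individual}_{.value}", names_vary = "slowest"
    )
  overall <- aggregates |>
    transmute(
      taxon = .data$taxon,
      overall_M = round_half_up(.data$overall_mean, 1),
      overall_CV = round_half_up(.data$overall_cv),
      mean_CV = round_half_up(.data$mean_cv)
    )
  left_join(per_ind, overall, by = "taxon") |>
    arrange(desc(.data$overall_M))
}

#' Anomaly-from-mean series
#'
#' For every sample, the deviation of each taxon's relative abundance from
#' that individual's temporal mean, with the +-1 and +-2 SD band edges.
#'
#' @param x An `abund_tbl` with `individual` labels.
#' @return Tibble: sample, individual, timepoint (if present), taxon,
#'   abundance, mean, anomaly, lo1, hi1, lo2, hi2 (on the input scale).
#' @export
anomaly_series <- function(x) {
  stats <- per_individual_stats(x, percent_scale = FALSE)
  grid <- complete_grid(x)
  as_tibble(grid) |>
    left_join(
      as_tibble(stats)[c("individual", "taxon", "mean", "sd")],
      by = c("individual", "taxon")
    ) |>
    mutate(
      anomaly = .data$abundance - .data$mean,
      lo1 = .data$mean - .data$sd, hi1 = .data$mean + .data$sd,
      lo2 = .data$mean - 2 * .data$sd, hi2 = .data$mean + 2 * .data$sd
    )
}

#' Within-genus oligotype profile
#'
#' Renormalizes oligotype abundances by the per-sample total abundance of
#' their genus, giving each oligotype's share of the genus (the "abundance
#' relative to the genus" view). Samples where the genus is absent are
#' excluded and reported in the `excluded_samples` attribute.
#'
#' @param x An oligotype-level `abund_tbl`.
#' @param genus Genus name.
#' @param taxonomy Tibble mapping oligotypes to genera: columns `node_id`
#'   (or `taxon`) and `genus` (e.g. from [assign_taxonomy()]).
#' @return An `abund_tbl` (level oligotype) restricted to the genus, each
#'   sample summing to 1 over the genus's oligotypes.
#' @export
within_genus_profile <- function(x, genus, taxonomy) {
  taxonomy <- as_tibble(taxonomy)
  if (!"node_id" %in% names(taxonomy) && "taxon" %in% names(taxonomy)) {
    taxonomy <- rename(taxonomy, node_id = "taxon")
  }
  members <- taxonomy$node_id[!is.na(taxonomy$genus) & taxonomy$genus == genus]
  members <- intersect(members, unique(x$taxon))
  if (length(members) == 0) {
    abort(paste0("genus not present in table: ", genus))
  }
  m <- abund_matrix(complete_grid(x))[, members, drop = FALSE]
  totals <- rowSums(m)
  excluded <- rownames(m)[totals == 0]
  keep <- totals > 0
  out <- abund_from_matrix(
    m[keep, , drop = FALSE] / totals[keep],
    level = "oligotype", meta = sample_meta(x)
  )
  attr(out, "genus") <- genus
  attr(out, "excluded_samples") <- excluded
  out
}

#' Abundant (individual, oligotype) pairs
#'
#' Pairs whose per-individual mean (percent) is strictly greater than the
#' threshold: the "mean > 10% of the genus in some individual" rule.
#'
#' @param stats A [per_individual_stats()] tibble (percent scale).
#' @param threshold Percent threshold (default 10).
#' @return The subset of `stats` rows that qualify; the union of qualifying
#'   taxa is attached as the `taxon_union` attribute.
#' @export
abundant_oligotypes <- function(stats, threshold = 10) {
  out <- filter(as_tibble(stats), .data$mean > threshold)
  attr(out, "taxon_union") <- sort(unique(out$taxon))
  out
}

#' Fingerprint contrast: within-mouth vs overall CV
#'
#' The core stability statistic: among (individual, oligotype) pairs where
#' the oligotype is abundant (per-individual mean above `threshold`
#' percent), the unweighted mean within-individual CV; and for the union of
#' oligotypes abundant in at least one individual, the unweighted mean of
#' the all-samples (overall) CV. A large gap between the two says that
#' abundant oligotypes are stable within a mouth but differ between mouths.
#'
#' @param stats A [per_individual_stats()] tibble (percent scale).
#' @param aggregates The matching [aggregate_stats()] tibble.
#' @param threshold Percent abundance threshold (default 10).
#' @return One-row tibble: `mean_abundant_cv`, `mean_overall_cv` (both
#'   rounded to the nearest integer), `n_abundant_pairs`, `n_oligotypes`.
#' @export
fingerprint_summary <- function(stats, aggregates, threshold = 10) {
  ab <- abundant_oligotypes(stats, threshold)
  if (nrow(ab) == 0) abort("no abundant (individual, oligotype) pairs")
  union_taxa <- attr(ab, "taxon_union")
  overall <- aggregates$overall_cv[match(union_taxa, aggregates$taxon)]
  tibble(
    mean_abundant_cv = round_half_up(mean(ab$cv, na.rm = TRUE)),
    mean_overall_cv = round_half_up(mean(overall, na.rm = TRUE)),
    n_abundant_pairs = nrow(ab),
    n_oligotypes = length(union_taxa)
  )
}

# Bray-Curtis between two abundance vectors
bc_pair <- function(x, y) {
  denom <- sum(x + y)
  if (denom == 0) return(NA_real_)
  sum(abs(x - y)) / denom
}

#' Nearest-centroid individual identification for one held-out sample
#'
#' Predicts which individual a held-out sample belongs to as the individual
#' whose mean profile (over its remaining samples) is closest in
#' Bray-Curtis dissimilarity. Ties break by individual label order.
#'
#' @param x An `abund_tbl` with `individual` labels.
#' @param held_out Sample id to hold out.
#' @return The predicted individual label (character scalar).
#' @export
fingerprint_classify <- function(x, held_out) {
  m <- abund_matrix(complete_grid(x))
  if (!held_out %in% rownames(m)) abort(paste0("unknown sample: ", held_out))
  meta <- sample_meta(x)
  ind_of <- setNames(as.character(meta$individual), meta$sample)
  rest <- setdiff(rownames(m), held_out)
  inds <- sort(unique(ind_of[rest]))
  sizes <- table(ind_of[rest])
  if (any(sizes < 2)) {
    abort("every individual needs >= 2 samples besides the held-out one")
  }
  centroids <- t(vapply(
    inds,
    function(i) colMeans(m[rest[ind_of[rest] == i], , drop = FALSE]),
    numeric(ncol(m))
  ))
  d <- apply(centroids, 1, bc_pair, y = m[held_out, ])
  inds[which.min(d)] # first minimum = label-order tie-break
}

#' Leave-one-out individual-identification accuracy
#'
#' Applies [fingerprint_classify()] to every sample in turn.
#'
#' @param x An `abund_tbl` with `individual` labels.
#' @return List: `accuracy` (fraction correct) and `predictions` (tibble of
#'   sample, truth, predicted).
#' @export
fingerprint_loo <- function(x) {
  meta <- sample_meta(x)
  preds <- purrr::map_chr(meta$sample, function(s) fingerprint_classify(x, s))
  tbl <- tibble(
    sample = meta$sample,
    truth = as.character(meta$individual),
    predicted = preds
  )
  list(accuracy = mean(tbl$truth == tbl$predicted), predictions = tbl)
}
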