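eight_series <- function(values, taxon = "g1", individual = "A") {
  tibble::tibble(
    sample = paste0(individual, "_T", seq_along(values)),
    individual = individual,
    taxon = taxon,
    abundance = values
  )
}

test_that("single-spike series pins the n-1 CV convention (283%)", {
  for (x in c(0.004, 0.2, 0.9)) {
    st <- per_individual_stats(eight_series(c(x, rep(0, 7))))
    expect_equal(st$cv, 100 * 2 * sqrt(2), tolerance = 1e-12)
    expect_equal(round_half_up(st$cv), 283)
  }
  # n-sample generalization: CV = 100 * sqrt(n)
  for (n in c(4, 16)) {
    st <- per_individual_stats(eight_series(c(1, rep(0, n - 1))))
    expect_equal(st$cv, 100 * sqrt(n), tolerance = 1e-12)
  }
})

test_that("mean, SD and CV follow hand arithmetic", {
  # constant series: CV 0
  st0 <- per_individual_stats(eight_series(rep(0.25, 8)))
  expect_equal(st0$cv, 0)
  # (2, 4)%: mean 3, sd sqrt(2), CV 47%
  st <- per_individual_stats(eight_series(c(0.02, 0.04)))
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(round_half_up(st$cv), 47)
  # zero-mean series: CV undefined
  stz <- per_individual_stats(dplyr::bind_rows(
    eight_series(c(0, 0)), eight_series(c(0.01, 0.03), taxon = "g2")
  ))
  expect_true(is.na(stz$cv[stz$taxon == "g1"]))
  # fewer than two samples per individual is an error
  expect_error(
    per_individual_stats(eight_series(0.5)),
    "fewer than 2"
  )
})

test_that("aggregates reproduce printed-table conventions from exact series", {
  ref <- plaque_reference_stats("genus")
  cor_rows <- dplyr::filter(ref$stats, taxon == "Cor")
  tbl <- abund_table(series_from_mean_cv(cor_rows), level = "genus")
  st <- per_individual_stats(tbl)
  ag <- aggregate_stats(st, tbl)
  # per-individual stats recover the constructed means and CVs
  key <- dplyr::left_join(
    st, cor_rows, by = c("individual", "taxon"), suffix = c("", "_ref")
  )
  expect_equal(key$mean, key$mean_ref, tolerance = 1e-9)
  expect_equal(key$cv, key$cv_ref, tolerance = 1e-9)
  # overall mean = mean of per-individual means under equal group sizes
  expect_equal(round_half_up(ag$overall_mean, 1), 13.1)
  # unweighted mean of per-individual CVs
  expect_equal(round_half_up(ag$mean_cv), 49)
  # all-equal CVs aggregate to that CV
  flat <- dplyr::mutate(cor_rows, cv = 30)
  tblf <- abund_table(series_from_mean_cv(flat), level = "genus")
  agf <- aggregate_stats(per_individual_stats(tblf), tblf)
  expect_equal(round_half_up(agf$mean_cv), 30)
})

test_that("anomalies center each individual series at zero", {
  tbl <- abund_table(
    dplyr::bind_rows(
      eight_series(c(0.10, 0.20)),
      eight_series(runif(2), taxon = "g2"),
      eight_series(runif(4), individual = "B"),
      eight_series(runif(4), taxon = "g2", individual = "B")
    ),
    level = "genus"
  )
  an <- anomaly_series(tbl)
  sums <- an |>
    dplyr::group_by(individual, taxon) |>
    dplyr::summarise(s = sum(anomaly), .groups = "drop")
  expect_true(all(abs(sums$s) < 1e-9))
  # hand case: (10, 20)% -> (-5, +5)%
  a <- dplyr::filter(an, individual == "A", taxon == "g1")
  expect_equal(sort(a$anomaly), c(-0.05, 0.05))
  # constant series: all anomalies zero, bands collapse onto the mean
  const <- abund_table(eight_series(rep(0.3, 5)), level = "genus")
  ac <- anomaly_series(const)
  expect_true(all(ac$anomaly == 0))
  expect_true(all(ac$lo2 == 0.3 & ac$hi2 == 0.3))
})

test_that("within-genus profiles renormalize by the genus total", {
  m <- rbind(
    S1 = c(OT1 = 0.05, OT2 = 0.05, OT3 = 0.40),
    S2 = c(OT1 = 0.10, OT2 = 0.00, OT3 = 0.50),
    S3 = c(OT1 = 0.00, OT2 = 0.00, OT3 = 1.00)
  )
  tax <- tibble::tibble(node_id = c("OT1", "OT2", "OT3"),
                        genus = c("Cory", "Cory", "Strep"))
  prof <- within_genus_profile(toy_abund(m, level = "oligotype"), "Cory", tax)
  pm <- abund_matrix(prof)
  expect_equal(unname(pm["S1", c("OT1", "OT2")]), c(0.5, 0.5))
  expect_equal(unname(pm["S2", c("OT1", "OT2")]), c(1, 0))
  # zero-genus sample excluded with a flag, not a division error
  expect_equal(attr(prof, "excluded_samples"), "S3")
  # single-oligotype genus: profile identically 1
  ps <- within_genus_profile(toy_abund(m, level = "oligotype"), "Strep", tax)
  expect_true(all(abund_matrix(ps) == 1))
  expect_error(
    within_genus_profile(toy_abund(m, level = "oligotype"), "Nope", tax),
    "Nope"
  )
})

test_that("abundant-oligotype selection is strictly greater than threshold", {
  st <- per_individual_stats(abund_table(dplyr::bind_rows(
    eight_series(rep(0.354, 4), taxon = "hi"), # mean 35.4%
    eight_series(rep(0.014, 4), taxon = "lo"), # mean 1.4%
    eight_series(rep(0.100, 4), taxon = "edge") # mean exactly 10%
  ), level = "oligotype"))
  ab <- abundant_oligotypes(st, threshold = 10)
  expect_setequal(ab$taxon, "hi")
})

test_that("fingerprint summary contrasts within-mouth and overall CV", {
  # all oligotypes constant within individuals -> abundant CV 0
  tbl <- abund_table(dplyr::bind_rows(
    eight_series(rep(0.6, 3), taxon = "o1", individual = "A"),
    eight_series(rep(0.4, 3), taxon = "o2", individual = "A"),
    eight_series(rep(0.1, 3), taxon = "o1", individual = "B"),
    eight_series(rep(0.9, 3), taxon = "o2", individual = "B")
  ), level = "oligotype")
  st <- per_individual_stats(tbl)
  ag <- aggregate_stats(st, tbl)
  fp <- fingerprint_summary(st, ag)
  expect_equal(fp$mean_abundant_cv, 0)
  expect_gt(fp$mean_overall_cv, 0) # individuals differ -> pooled CV positive
  expect_equal(fp$n_abundant_pairs, 3) # B's o1 sits exactly at 10%: excluded
  expect_error(
    fingerprint_summary(dplyr::filter(st, mean > 1000), ag),
    "no abundant"
  )
})

test_that("nearest-centroid identification handles the clean cases", {
  m <- rbind(
    A_T1 = c(x = 1, y = 0, z = 0),
    A_T2 = c(x = 1, y = 0, z = 0),
    A_T3 = c(x = 1, y = 0, z = 0),
    B_T1 = c(x = 0, y = 1, z = 0),
    B_T2 = c(x = 0, y = 1, z = 0),
    B_T3 = c(x = 0, y = 1, z = 0)
  )
  tbl <- toy_abund(m, level = "oligotype",
                   individuals = rep(c("A", "B"), each = 3))
  expect_equal(fingerprint_classify(tbl, "A_T2"), "A")
  expect_equal(fingerprint_classify(tbl, "B_T3"), "B")
  loo <- fingerprint_loo(tbl)
  expect_equal(loo$accuracy, 1)
  # a single individual is always predicted
  one <- toy_abund(m[1:3, ], level = "oligotype", individuals = rep("A", 3))
  expect_equal(fingerprint_classify(one, "A_T1"), "A")
})
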