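test_that("config validation enforces the documented invariants", {
  expect_error(synthetic_config(n_individuals = 0), ">= 1")
  expect_error(synthetic_config(base_error_rate = 0.3), "0.25")
  expect_error(synthetic_config(fluctuation_alpha = 0), "> 0")
  expect_error(
    synthetic_config(read_length = 10, oligos_per_genus = 11),
    "plant distinct variants"
  )
  cfg <- synthetic_config(n_genera = 3, oligos_per_genus = c(4, 2))
  expect_equal(cfg$oligos_per_genus, c(4L, 2L, 4L)) # recycled
})

test_that("the planted library has the promised structure", {
  # degenerate: one oligotype per genus, root only
  cfg1 <- synthetic_config(n_genera = 2, oligos_per_genus = 1, seed = 3)
  t1 <- generate_oligotype_library(cfg1)
  expect_equal(nrow(t1$oligos), 2)
  # 24 distinct variants in one genus (the most diverse-genus case)
  cfg24 <- synthetic_config(n_genera = 1, oligos_per_genus = 24, seed = 3)
  t24 <- generate_oligotype_library(cfg24)
  expect_equal(nrow(t24$oligos), 24)
  expect_equal(anyDuplicated(t24$oligos$seq), 0)
  expect_true(all(nchar(t24$oligos$seq) == 336))
  # every pair differs at >= 1 column; within-genus pairs stay >= 97% alike
  cm <- do.call(rbind, strsplit(t24$oligos$seq, ""))
  for (i in 2:24) {
    diffs <- sum(cm[1, ] != cm[i, ])
    expect_gte(diffs, 1)
    expect_gte((336 - diffs) / 336, 0.97)
  }
  # two species planted within a large genus
  expect_equal(length(unique(t24$oligos$species)), 2)
  # determinism: same seed, byte-identical library
  expect_identical(t24$oligos, generate_oligotype_library(cfg24)$oligos)
})

test_that("individual profiles are sparse, normalized simplex draws", {
  cfg <- synthetic_config(n_individuals = 4, seed = 5)
  tr <- generate_individual_profiles(cfg, generate_oligotype_library(cfg))
  sums <- tr$profiles |>
    dplyr::group_by(individual) |>
    dplyr::summarise(s = sum(mean_prop))
  expect_equal(sums$s, rep(1, 4), tolerance = 1e-9)
  gsums <- tr$genus_profiles |>
    dplyr::group_by(individual) |>
    dplyr::summarise(s = sum(mean_prop))
  expect_equal(gsums$s, rep(1, 4), tolerance = 1e-9)
  # Monte-Carlo oracle on the Dirichlet: with concentration 0.1 and K = 20,
  # the expected number of components above 10% is small (well under K/2)
  set.seed(99)
  draws <- rdirichlet(1e4, rep(0.1, 20))
  mc_expected <- mean(rowSums(draws > 0.10))
  expect_lt(mc_expected, 10)
  cfg20 <- synthetic_config(
    n_individuals = 8, n_genera = 1, oligos_per_genus = 20,
    profile_sparsity = 0.1, seed = 6
  )
  tr20 <- generate_individual_profiles(cfg20, generate_oligotype_library(cfg20))
  per_ind <- tr20$profiles |>
    dplyr::group_by(individual) |>
    dplyr::summarise(n_dom = sum(within_genus > 0.10))
  # each individual's dominant set is a small subset, near the MC expectation
  expect_lt(mean(per_ind$n_dom), 10)
  # distinct individuals draw different dominant subsets (MC says overlap of
  # full 20-oligotype dominant sets is vanishingly unlikely)
  dom_sets <- tr20$profiles |>
    dplyr::filter(within_genus > 0.10) |>
    dplyr::group_by(individual) |>
    dplyr::summarise(set = paste(sort(oligo_id), collapse = ","))
  expect_gt(dplyr::n_distinct(dom_sets$set), 1)
})

test_that("the uniform limit removes the fingerprint", {
  cfg <- synthetic_config(
    n_individuals = 3, n_genera = 1, oligos_per_genus = 10,
    profile_sparsity = 1e5, seed = 8
  )
  tr <- generate_individual_profiles(cfg, generate_oligotype_library(cfg))
  expect_true(all(abs(tr$profiles$within_genus - 0.1) < 0.02))
})

test_that("reads carry sample labels, fixed length and legal alphabet", {
  sim <- small_sim(seed = 13, epsilon = 0.01, reads = 300)
  reads <- sim$reads$reads
  expect_true(all(nchar(reads$seq) == 336))
  chars <- unique(unlist(strsplit(reads$seq[1:50], "")))
  expect_true(all(chars %in% c("A", "C", "G", "T", "-")))
  expect_true(all(reads$sample %in% sim$truth$sample_info$sample))
  # read ids encode sample, individual, timepoint, serial
  expect_true(all(grepl("^[^:]+:[^:]+:[^:]+:\\d+$", reads$read_id)))
  # determinism end to end
  sim2 <- small_sim(seed = 13, epsilon = 0.01, reads = 300)
  expect_identical(sim$reads$reads, sim2$reads$reads)
  expect_identical(sim$truth$sample_proportions, sim2$truth$sample_proportions)
})

test_that("zero-error single-oligotype samples are exact copies", {
  sim <- small_sim(
    seed = 19, epsilon = 0, reads = 200,
    n_genera = 1, oligos_per_genus = 1, n_individuals = 1, n_timepoints = 2
  )
  expect_true(all(sim$reads$reads$seq == sim$truth$oligos$seq))
})

test_that("stable-limit samples track the individual mean profile", {
  sim <- small_sim(
    seed = 23, epsilon = 0, reads = 4000,
    fluctuation_alpha = 1e9, n_individuals = 1, n_timepoints = 2
  )
  mu <- sim$truth$profiles$mean_prop[order(sim$truth$profiles$oligo_id)]
  props <- sim$truth$sample_proportions |>
    dplyr::filter(sample == sample[1]) |>
    dplyr::arrange(oligo_id)
  expect_equal(props$proportion, mu, tolerance = 1e-3)
})

test_that("per-sample depths match the stated normal summary", {
  set.seed(77)
  depths <- draw_sample_depths(64)
  se <- 923.8 / sqrt(64)
  expect_lt(abs(mean(depths) - 5618), 3 * se)
  expect_true(all(draw_sample_depths(50, mean = 1, sd = 100) >= 1))
})

test_that("realized counts fit the drawn proportions (chi-square GOF)", {
  pvals <- vapply(1:20, function(seed) {
    sim <- small_sim(seed = seed, epsilon = 0, reads = 2000,
                     n_individuals = 1, n_timepoints = 1,
                     profile_sparsity = 2)
    cnt <- dplyr::left_join(
      sim$truth$sample_counts, sim$truth$sample_proportions,
      by = c("sample", "oligo_id")
    )
    # pool rare categories so expected counts are viable
    n <- sum(cnt$count)
    keep <- cnt$proportion * n >= 5
    obs <- c(cnt$count[keep], sum(cnt$count[!keep]))
    pr <- c(cnt$proportion[keep], sum(cnt$proportion[!keep]))
    drop0 <- pr > 0
    suppressWarnings(stats::chisq.test(obs[drop0], p = pr[drop0] / sum(pr[drop0]))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("temporal CV decreases monotonically in the fluctuation precision", {
  cv_at <- function(alpha) {
    sim <- small_sim(
      seed = 37, epsilon = 0, reads = 200, fluctuation_alpha = alpha,
      n_individuals = 1, n_timepoints = 30, profile_sparsity = 2
    )
    tab <- truth_abundance_table(sim$truth, "oligotype")
    st <- per_individual_stats(tab)
    mean(st$cv[st$mean > 5], na.rm = TRUE)
  }
  cvs <- vapply(c(5, 50, 500), cv_at, numeric(1))
  expect_true(cvs[1] > cvs[2] && cvs[2] > cvs[3])
})
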