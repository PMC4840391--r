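mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

test_that("column entropy matches closed forms", {
  expect_equal(column_entropy(rep("A", 4), 1), 0)
  expect_equal(column_entropy(c(rep("A", 50), rep("C", 50)), 1), 1)
  # 60/20/20 split: -0.6 log2 0.6 - 2 * 0.2 log2 0.2
  seqs <- c(rep("A", 60), rep("C", 20), rep("G", 20))
  expect_equal(column_entropy(seqs, 1), 1.371, tolerance = 5e-4)
  # weighted form agrees with expansion
  expect_equal(
    column_entropy(c("A", "C", "G"), 1, weights = c(60, 20, 20)),
    column_entropy(seqs, 1)
  )
  expect_error(column_entropy(c("AC", "AC"), 3), "out of range")
})

test_that("two-variant mixtures split or are filtered by M as enumerated", {
  x <- paste(rep("A", 30), collapse = "")
  y <- mutate_at(x, 7, "T")
  # both variants above M: two nodes with exact counts
  r1 <- med_decompose(toy_pool(list(seq = x, n = 100), list(seq = y, n = 80)),
    M = 60, V = 3
  )
  expect_equal(nrow(r1$nodes), 2)
  expect_equal(sort(r1$nodes$n_reads), c(80, 100))
  expect_setequal(r1$nodes$representative, c(x, y))
  expect_equal(r1$accounting$n_removed_min_abundance, 0)
  # minority variant below M: its whole node is discarded
  r2 <- med_decompose(toy_pool(list(seq = x, n = 100), list(seq = y, n = 30)),
    M = 60, V = 3
  )
  expect_equal(nrow(r2$nodes), 1)
  expect_equal(r2$nodes$n_reads, 100)
  expect_equal(r2$nodes$representative, x)
  expect_equal(r2$accounting$n_removed_min_abundance, 30)
})

test_that("identical reads form a single clean node", {
  x <- paste(rep("G", 20), collapse = "")
  r <- med_decompose(toy_pool(list(seq = x, n = 200)), M = 60, V = 3)
  expect_equal(nrow(r$nodes), 1)
  expect_equal(r$nodes$n_reads, 200)
  expect_equal(r$nodes$max_entropy, 0)
  expect_equal(r$accounting$n_removed_min_abundance, 0)
  expect_equal(r$accounting$n_removed_max_variation, 0)
})

test_that("representative is the modal sequence with lexicographic ties", {
  expect_equal(node_representative("ACGT", 5), "ACGT")
  expect_equal(node_representative(c("TTTT", "AAAA"), c(10, 3)), "TTTT")
  expect_equal(node_representative(c("TTTT", "AAAA"), c(5, 5)), "AAAA")
  expect_error(node_representative(character(), numeric()), "empty")
})

test_that("minimum substantive abundance boundary is discard-below-M", {
  nodes <- list(
    tibble::tibble(seq = "AAAA", n = 60), # exactly M: retained
    tibble::tibble(seq = "CCCC", n = 59), # below M: discarded
    tibble::tibble(seq = c("GGGG", "GGGT"), n = c(100, 40))
  )
  fa <- filter_min_abundance(nodes, M = 60)
  expect_equal(fa$keep, c(TRUE, FALSE, TRUE))
  expect_equal(fa$n_removed, 59)
  # survivors are exactly those with top unique count >= M
  tops <- c(60, 59, 100)
  expect_equal(fa$keep, tops >= 60)
})

test_that("maximum variation boundary keeps <= V mismatches", {
  x <- paste(rep("A", 20), collapse = "")
  v3 <- mutate_at(mutate_at(mutate_at(x, 1, "C"), 5, "C"), 9, "C")
  v4 <- mutate_at(v3, 13, "C")
  node <- tibble::tibble(seq = c(x, v3, v4), n = c(50, 5, 5))
  fv <- filter_max_variation(node, V = 3)
  expect_equal(fv$representative, x)
  expect_setequal(fv$node$seq, c(x, v3)) # 3 diffs kept, 4 removed
  expect_equal(fv$n_removed, 5)
  # a gap opposite a base counts as a difference
  g4 <- paste0("----", substr(x, 5, 20))
  fg <- filter_max_variation(tibble::tibble(seq = c(x, g4), n = c(9, 1)), V = 3)
  expect_equal(fg$n_removed, 1)
})

test_that("per-read error removal rate matches the binomial closed form", {
  eps <- 0.01
  sim <- small_sim(
    seed = 42, epsilon = eps, reads = 1000,
    n_genera = 1, oligos_per_genus = 1, n_individuals = 2, n_timepoints = 2
  )
  # raise m so error columns cannot split the single planted node and the
  # V criterion alone accounts for removals
  r <- med_decompose(sim$reads, M = 10, V = 3, m = 0.5)
  n <- r$accounting$n_input
  observed <- r$accounting$n_removed_max_variation / n
  expected <- 1 - pbinom(3, 336, eps)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("read accounting is conserved on fuzzed inputs", {
  set.seed(202)
  for (trial in 1:6) {
    base <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
      collapse = ""
    )
    n <- sample(50:300, 1)
    seqs <- vapply(seq_len(n), function(i) {
      s <- base
      k <- rbinom(1, 6, 0.3)
      for (p in sample(25, k)) {
        s <- mutate_at(s, p, sample(c("A", "C", "G", "T", "-"), 1))
      }
      s
    }, character(1))
    r <- med_decompose(toy_reads(seqs), M = sample(2:40, 1), V = sample(0:3, 1))
    a <- r$accounting
    expect_equal(
      a$n_input,
      a$n_retained + a$n_removed_min_abundance + a$n_removed_max_variation
    )
    expect_equal(a$n_retained, sum(r$nodes$n_reads))
    expect_equal(a$n_retained, sum(r$counts$count))
  }
})

test_that("decomposition is invariant to read order", {
  sim <- small_sim(seed = 5, epsilon = 0.002, reads = 400)
  reads <- sim$reads$reads
  shuffled <- reads[sample(nrow(reads)), ]
  r1 <- med_decompose(aligned_reads(reads, sim$reads$samples), M = 20, V = 3)
  r2 <- med_decompose(aligned_reads(shuffled, sim$reads$samples), M = 20, V = 3)
  expect_equal(r1$nodes, r2$nodes)
  expect_equal(
    dplyr::arrange(r1$counts, node_id, sample),
    dplyr::arrange(r2$counts, node_id, sample)
  )
})

test_that("error-free planted communities are recovered exactly", {
  sim <- small_sim(seed = 11, epsilon = 0)
  r <- med_decompose(sim$reads, M = 60, V = 3)
  truth <- sim$truth
  # sequences: every planted oligotype is a representative and vice versa
  expect_setequal(r$nodes$representative, truth$oligos$seq)
  expect_equal(r$accounting$n_removed_min_abundance, 0)
  expect_equal(r$accounting$n_removed_max_variation, 0)
  # per-sample counts equal the multinomial draws
  node_of <- setNames(
    r$nodes$node_id,
    truth$oligos$oligo_id[match(r$nodes$representative, truth$oligos$seq)]
  )
  got <- dplyr::arrange(r$counts, node_id, sample)
  want <- truth$sample_counts |>
    dplyr::filter(count > 0) |>
    dplyr::transmute(node_id = unname(node_of[oligo_id]), sample, count) |>
    dplyr::arrange(node_id, sample)
  expect_equal(got$count, want$count)
})

test_that("surviving nodes are below the entropy threshold at convergence", {
  sim <- small_sim(seed = 9, epsilon = 0.003, reads = 600)
  r <- med_decompose(sim$reads, M = 30, V = 3, m = 0.0965)
  expect_true(all(r$nodes$max_entropy <= 0.0965))
})

test_that("empty input yields an empty result with zero counts", {
  r <- med_decompose(tibble::tibble(
    read_id = character(), sample = character(), seq = character()
  ))
  expect_equal(nrow(r$nodes), 0)
  expect_equal(r$accounting$n_input, 0)
  expect_equal(r$accounting$n_retained, 0)
})
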