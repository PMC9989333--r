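test_that("pairwise coalescence times average 2N generations", {
  m <- one_pop_model(500)
  tm <- vapply(1:2000, function(i) {
    tmrca(simulate_genealogy(m, c(pop = 2), seed = i))
  }, numeric(1))
  # E[T2] = 2N, SD[T2] = 2N
  expect_lt(abs(mean(tm) - 1000), 3 * 1000 / sqrt(2000))
})

test_that("genealogies are reproducible and structurally sound", {
  m <- two_pop_model(split = 2000)
  g1 <- simulate_genealogy(m, c(A = 6, B = 6), seed = 99)
  g2 <- simulate_genealogy(m, c(A = 6, B = 6), seed = 99)
  expect_identical(g1$node_time, g2$node_time)
  expect_identical(g1$child1, g2$child1)

  # leaves at time zero, parents strictly older, single root
  expect_true(all(g1$node_time[1:12] == 0))
  non_root <- which(g1$parent > 0)
  expect_length(non_root, 2 * 12 - 2)
  expect_true(all(g1$node_time[g1$parent[non_root]] > g1$node_time[non_root]))

  expect_error(simulate_genealogy(m, c(A = 1)), "at least 2")

  # no between-population coalescence more recent than the split
  for (seed in 1:25) {
    g <- simulate_genealogy(m, c(A = 5, B = 5), seed = seed)
    ls <- mutspectra:::leaf_sets(g)
    for (node in (g$n + 1):(2 * g$n - 1)) {
      pops <- unique(g$leaf_pop[ls[[node]]])
      if (length(pops) > 1) expect_gte(g$node_time[node], 2000)
    }
  }

  # isolated populations with no joining split are rejected up front
  lonely <- population_model(list(A = list(epoch(0, 100)),
                                  B = list(epoch(0, 100))))
  expect_error(simulate_genealogy(lonely, c(A = 2, B = 2), seed = 1),
               "join all populations")
})

test_that("mutation placement matches Watterson's expectation", {
  w <- quick_world(len = 50002, rate = 1e-6)
  m <- one_pop_model(1000)
  theta_l <- 4 * 1000 * 1e-6 * 50000
  expected <- theta_l * sum(1 / (1:9))
  S <- vapply(1:300, function(i) {
    g <- simulate_genealogy(m, c(pop = 10), seed = i)
    n_variants(place_mutations(g, w$seq, w$mat, seed = i + 5000))
  }, numeric(1))
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)) + 0.01 * expected)

  # zero-length genealogy yields an empty table
  g <- simulate_genealogy(m, c(pop = 10), seed = 1)
  g$segments$end <- g$segments$start
  empty <- place_mutations(g, w$seq, w$mat, seed = 1)
  expect_equal(n_variants(empty), 0)

  # unnormalized matrices are refused
  expect_error(place_mutations(g, w$seq, build_uniform_matrix()),
               "normalized")
})

test_that("a fold-shifted type is proportionally enriched among variants", {
  s <- generate_sequence(100002, seed = 21)
  shifted <- normalize_overall_rate(
    apply_fold_shift(build_uniform_matrix(), "TCC>T", 2), s, 2e-6)
  m <- one_pop_model(1000)
  tabs <- lapply(1:20, function(i) {
    g <- simulate_genealogy(m, c(pop = 10), seed = 100 + i)
    place_mutations(g, s, shifted, seed = 200 + i)
  })
  labs <- unlist(lapply(tabs, classify_mutation))
  counts <- table(factor(labs, levels = mutation_types()$label))
  # weight by triplet availability: compare per-site incidence
  cc <- context_counts(s)
  per_site <- as.numeric(counts) / cc[mutation_types()$triplet]
  names(per_site) <- mutation_types()$label
  ratio <- per_site["TCC>T"] / mean(per_site[names(per_site) != "TCC>T"])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("folded site-frequency spectrum matches the neutral shape", {
  # Pooled SFS shares carry large between-genealogy variance (a few long
  # branches dominate), so the tolerance reflects the Monte-Carlo noise of
  # ~1500 independent genealogies, not per-site binomial error.
  w <- quick_world(len = 10002, rate = 2e-6, seed = 31)
  m <- one_pop_model(500)
  n <- 8
  folded <- numeric(n %/% 2)
  for (i in 1:1500) {
    g <- simulate_genealogy(m, c(pop = n), seed = 3000 + i)
    tab <- place_mutations(g, w$seq, w$mat, seed = 4000 + i)
    if (n_variants(tab) == 0) next
    cnt <- allele_counts(tab)[, "pop"]
    f <- pmin(cnt, n - cnt)
    folded <- folded + tabulate(f, nbins = n %/% 2)
  }
  eta <- vapply(1:(n %/% 2), function(i) {
    (1 / i + 1 / (n - i)) / (1 + as.integer(2 * i == n))
  }, numeric(1))
  expect_gt(sum(folded), 10000)
  got <- folded / sum(folded)
  want <- eta / sum(eta)
  expect_lt(max(abs(got - want)), 0.05)
})

test_that("haplotypes within a population are exchangeable", {
  # each haplotype carries, on average, the same number of derived alleles
  w <- quick_world(len = 10002, rate = 5e-6, seed = 41)
  m <- one_pop_model(300)
  per_hap <- matrix(0, nrow = 200, ncol = 6)
  for (i in 1:200) {
    g <- simulate_genealogy(m, c(pop = 6), seed = 7000 + i)
    tab <- place_mutations(g, w$seq, w$mat, seed = 8000 + i)
    per_hap[i, ] <- Matrix::colSums(tab$genotypes)
  }
  means <- colMeans(per_hap)
  se <- apply(per_hap, 2, sd) / sqrt(nrow(per_hap))
  grand <- mean(means)
  expect_true(all(abs(means - grand) < 4 * se))
})

test_that("windowed datasets are linear in length and reproducible", {
  m <- two_pop_model()
  w1 <- quick_world(len = 20002, rate = 2e-6, seed = 51)
  w2 <- quick_world(len = 40002, rate = 2e-6, seed = 51)
  S1 <- mean(vapply(1:10, function(i) {
    n_variants(simulate_dataset(m, w1$seq, w1$mat, c(A = 8, B = 8),
                                window_length = 5000, seed = i))
  }, numeric(1)))
  S2 <- mean(vapply(1:10, function(i) {
    n_variants(simulate_dataset(m, w2$seq, w2$mat, c(A = 8, B = 8),
                                window_length = 5000, seed = 100 + i))
  }, numeric(1)))
  expect_gt(S2 / S1, 1.6)
  expect_lt(S2 / S1, 2.4)

  t1 <- simulate_dataset(m, w1$seq, w1$mat, c(A = 8, B = 8), seed = 77)
  t2 <- simulate_dataset(m, w1$seq, w1$mat, c(A = 8, B = 8), seed = 77)
  expect_identical(t1$variants, t2$variants)
  expect_identical(as.matrix(t1$genotypes), as.matrix(t2$genotypes))
  expect_error(simulate_dataset(m, w1$seq, w1$mat, c(A = 8, B = 8),
                                window_length = 1e6), "exceeds")
})

test_that("the forward Wright-Fisher oracle honours its guards and contract", {
  one <- one_pop_model(50)
  sw <- generate_sequence(502, seed = 61)
  mw <- normalize_overall_rate(build_uniform_matrix(), sw, 1e-4)

  t1 <- forward_wf_oracle(one, c(pop = 10), sw, mw, seed = 5)
  t2 <- forward_wf_oracle(one, c(pop = 10), sw, mw, seed = 5)
  expect_identical(t1$variants, t2$variants)

  zero <- normalize_overall_rate(build_uniform_matrix(), sw, 0)
  expect_equal(n_variants(forward_wf_oracle(one, c(pop = 10), sw, zero,
                                            seed = 1)), 0)

  expect_error(forward_wf_oracle(one_pop_model(5000), c(pop = 10), sw, mw),
               "guard")
  grow <- population_model(list(pop = list(epoch(0, 50, growth_rate = 0.01))))
  expect_error(forward_wf_oracle(grow, c(pop = 4), sw, mw), "constant-size")

  counts <- allele_counts(t1)[, "pop"]
  expect_true(all(counts > 0 & counts < 10))
})

test_that("coalescent engine and forward oracle agree on segregating sites", {
  one <- one_pop_model(50)
  sw <- generate_sequence(502, seed = 62)
  mw <- normalize_overall_rate(build_uniform_matrix(), sw, 1e-4)
  reps <- 120
  s_wf <- vapply(1:reps, function(i) {
    n_variants(forward_wf_oracle(one, c(pop = 10), sw, mw, seed = 100 + i))
  }, numeric(1))
  s_co <- vapply(1:reps, function(i) {
    g <- simulate_genealogy(one, c(pop = 10), seed = 300 + i)
    n_variants(place_mutations(g, sw, mw, seed = 500 + i))
  }, numeric(1))
  se <- sqrt(var(s_wf) / reps + var(s_co) / reps)
  expect_lt(abs(mean(s_wf) - mean(s_co)), 3 * se)
})
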