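# Small helper: build a stranded-192 spectrum with given leading counts.
spectrum_from_counts <- function(counts) {
  counts <- as.integer(c(counts, rep(0L, 192 - length(counts))))
  mutspectra:::new_spectrum(mutation_types()$label, counts, "stranded192")
}

test_that("the default scheme reproduces the published grid", {
  sch <- default_scheme()
  expect_length(sch$sizes, 57)  # 40 + 8 + 9
  expect_equal(min(sch$sizes), 5)
  expect_equal(max(sch$sizes), 10000)
  expect_equal(sch$replicates_per_size, 5)
  expect_true(all(diff(sch$sizes) > 0))
  expect_error(sampling_scheme(c(10, 10)), "strictly increasing")
  expect_error(sampling_scheme(10, 0), "replicates")
})

test_that("total_difference is the summed absolute proportion gap", {
  s1 <- spectrum_from_counts(c(500, 500))
  s2 <- spectrum_from_counts(c(250, 250, 500))
  expect_equal(total_difference(s1, s1), 0)
  expect_equal(total_difference(s1, s2), 1.0)  # |0.25| + |0.25| + |0.5|

  disjoint_a <- spectrum_from_counts(c(1000))
  disjoint_b <- spectrum_from_counts(c(0, 1000))
  expect_equal(total_difference(disjoint_a, disjoint_b), 2)

  expect_error(total_difference(collapse_strands(s1), s1),
               "different category spaces")
  expect_error(total_difference(spectrum_from_counts(0), s1), "empty")

  # metric properties on random spectra
  rand_spec <- function(seed) {
    spectrum_from_counts(withr::with_seed(
      seed, as.integer(stats::rmultinom(1, 500, rep(1, 192)))))
  }
  for (seed in 1:10) {
    a <- rand_spec(seed); b <- rand_spec(seed + 100); c <- rand_spec(seed + 200)
    expect_equal(total_difference(a, b), total_difference(b, a))
    expect_lte(total_difference(a, c),
               total_difference(a, b) + total_difference(b, c) + 1e-12)
    expect_gte(total_difference(a, b), 0)
  }
})

test_that("subsampling individuals recomputes counts and drops lost variants", {
  m <- two_pop_model()
  w <- quick_world(len = 30002, rate = 2e-6, seed = 71)
  tab <- simulate_dataset(m, w$seq, w$mat, c(A = 20, B = 20), seed = 72)

  # determinism
  s1 <- subsample_individuals(tab, "B", 5, seed = 9)
  s2 <- subsample_individuals(tab, "B", 5, seed = 9)
  expect_identical(s1$variants, s2$variants)
  expect_equal(sum(s1$haplotypes$population == "B"), 10)

  # without-replacement draw of the whole population is the identity
  full <- subsample_individuals(tab, "B", 10, seed = 1, replace = FALSE)
  spec_full <- compute_spectrum(private_segregating(full, "B"))
  spec_orig <- compute_spectrum(private_segregating(tab, "B"))
  expect_equal(spec_full$count, spec_orig$count)
  expect_equal(total_difference(spec_full, spec_orig), 0)

  # variants carried only by an unsampled individual disappear: replay the
  # seeded draw to learn which individual was left out
  hapB <- tab$haplotypes[tab$haplotypes$population == "B", ]
  inds <- unique(hapB$individual)
  chosen <- withr::with_seed(2, inds[sample.int(length(inds), 9)])
  left_out <- setdiff(inds, chosen)
  expect_length(left_out, 1)
  out_cols <- hapB$hap[hapB$individual == left_out]
  countsB <- allele_counts(tab)[, "B"]
  only_theirs <- which(countsB > 0 & countsB == Matrix::rowSums(
    tab$genotypes[, out_cols, drop = FALSE]))
  expect_gt(length(only_theirs), 0)
  sub <- subsample_individuals(tab, "B", 9, seed = 2, replace = FALSE)
  expect_length(intersect(tab$variants$pos[only_theirs], sub$variants$pos), 0)

  # sizes beyond the population are allowed with replacement
  big <- subsample_individuals(tab, "B", 50, seed = 3)
  expect_equal(sum(big$haplotypes$population == "B"), 100)
  expect_error(subsample_individuals(tab, "B", 0), ">= 1")
  expect_error(subsample_individuals(tab, "B", 50, replace = FALSE),
               "exceeds")
})

test_that("convergence curves shrink with sample size", {
  m <- two_pop_model()
  w <- quick_world(len = 50002, rate = 2e-6, seed = 81)
  tab <- simulate_dataset(m, w$seq, w$mat, c(A = 40, B = 40), seed = 82)
  sch <- sampling_scheme(c(2L, 8L, 32L), replicates_per_size = 4)
  cc <- convergence_curve(tab, "B", sch, seed = 83)
  expect_equal(nrow(cc), 12)
  expect_equal(cc$percent, 100 * cc$total_difference)
  expect_true(all(cc$total_difference >= 0 & cc$total_difference <= 2,
                  na.rm = TRUE))
  means <- tapply(cc$total_difference, cc$size, mean)
  expect_gt(means[["2"]], means[["32"]])
})
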