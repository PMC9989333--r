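# A hand-built variant table: 2 populations x 2 diploid individuals each,
# with rows covering the privacy cases.
toy_table <- function() {
  variants <- data.frame(
    pos = c(10L, 20L, 30L, 40L, 50L),
    triplet = c("TCC", "TCC", "ACG", "GGA", "TCT"),
    derived = c("T", "T", "A", "A", "G")
  )
  # haplotypes 1:4 = pop A, 5:8 = pop B
  g <- Matrix::sparseMatrix(
    i = c(1, 1,          # pos 10: A-private, count 2/4
          2, 2, 2, 2,    # pos 20: fixed derived in A
          3, 3, 3,       # pos 30: shared between A and B
          4,             # pos 40: B-private singleton
          5),            # pos 50: A-private singleton
    j = c(1, 2,
          1, 2, 3, 4,
          1, 2, 5,
          5,
          3),
    x = 1, dims = c(5, 8))
  hap <- data.frame(hap = 1:8,
                    population = rep(c("A", "B"), each = 4),
                    individual = rep(1:2, each = 2, times = 2))
  variant_table(variants, g, hap)
}

test_that("private_segregating keeps exactly the focal-private segregating rows", {
  tab <- toy_table()
  privA <- private_segregating(tab, "A")
  expect_equal(privA$variants$pos, c(10L, 50L))  # fixed-derived and shared removed
  privB <- private_segregating(tab, "B")
  expect_equal(privB$variants$pos, 40L)

  # privacy partitions: no row is private to two populations
  expect_length(intersect(privA$variants$pos, privB$variants$pos), 0)

  expect_error(private_segregating(tab, "C"), "not in table")
  one_pop <- variant_table(tab$variants, tab$genotypes,
                           transform(tab$haplotypes, population = "A"))
  expect_error(private_segregating(one_pop, "A"), "two populations")
})

test_that("classify_mutation maps contexts to the 192 categories", {
  expect_equal(classify_mutation("TCC", "T"), "TCC>T")
  expect_equal(classify_mutation("ACG", "A"), "ACG>A")
  expect_error(classify_mutation("ACG", "C"), "middle")
  expect_error(classify_mutation("AXG", "C"), "triplet")
})

test_that("spectra normalize, collapse, and flag emptiness", {
  tab <- toy_table()
  sp <- compute_spectrum(tab)
  expect_s3_class(sp, "spectrum")
  expect_equal(attr(sp, "total"), 5)
  expect_equal(sum(sp$proportion), 1)
  expect_equal(nrow(sp), 192)

  # TCC>T rows alone give proportion 1 there
  sp1 <- compute_spectrum(mutspectra:::filter_variants(tab, c(TRUE, TRUE,
                                                              FALSE, FALSE,
                                                              FALSE)))
  expect_equal(sp1$proportion[sp1$category == "TCC>T"], 1)

  c96 <- collapse_strands(sp)
  expect_equal(nrow(c96), 96)
  expect_equal(sum(c96$count), sum(sp$count))
  # TCC>T (5' TCC 3' -> 5' TTC 3') absorbs its reverse complement GGA>A
  expect_equal(c96$count[c96$category == "TCC>T"],
               sum(sp$count[sp$category %in% c("TCC>T", "GGA>A")]))
  expect_error(collapse_strands(c96), "already")

  # duplicating every row leaves proportions unchanged
  dup <- mutspectra:::filter_variants(tab, rep(1:5, 2))
  expect_equal(compute_spectrum(dup)$proportion, sp$proportion)

  empty <- mutspectra:::filter_variants(tab, rep(FALSE, 5))
  spe <- compute_spectrum(empty)
  expect_true(attr(spe, "empty"))
  expect_true(all(is.na(spe$proportion)))
  expect_equal(sum(spe$count), 0)
})

test_that("strand collapse pairs each type with its reverse complement", {
  mt <- mutation_types()$label
  partners <- revcomp_type(mt)
  expect_setequal(partners, mt)              # an involution on the 192 labels
  expect_equal(revcomp_type(partners), mt)   # applied twice = identity
  reps <- unique(unname(mutspectra:::.COLLAPSE_MAP[mt]))
  expect_length(reps, 96)
  expect_true(all(substr(reps, 2, 2) %in% c("C", "T")))
})

test_that("spectrum TSVs round-trip", {
  sp <- compute_spectrum(toy_table(), space = "collapsed96")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, tf)
  back <- read_spectrum(tf)
  expect_equal(back$count, sp$count)
  expect_equal(attr(back, "space"), "collapsed96")
})
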