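test_that("the uniform matrix is flat over all 192 types", {
  m <- build_uniform_matrix()
  expect_equal(nrow(m), 192)
  expect_length(unique(m$rate), 1)
  # conditional derived-base distribution is (1/3, 1/3, 1/3) everywhere
  s <- generate_sequence(1000, seed = 1)
  sr <- site_rate(s, 500, normalize_overall_rate(m, s, 1e-8))
  expect_equal(unname(sr$conditional), rep(1 / 3, 3))
  expect_equal(sr$total, 1e-8)
})

test_that("matrix tables round-trip and malformed tables are rejected", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  orig <- build_uniform_matrix()
  write_matrix(orig, tf)
  expect_equal(load_matrix(tf)$rate, orig$rate)

  shipped <- load_matrix(system.file("extdata/matrices/uniform_rates.tsv",
                                     package = "mutspectra"))
  expect_equal(shipped$rate / max(shipped$rate),
               orig$rate / max(orig$rate))

  full <- as.data.frame(orig)[c("triplet", "derived", "rate")]
  write.table(full[-1, ], tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_matrix(tf), "192")

  dup <- full
  dup[1, ] <- dup[2, ]
  write.table(dup, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_matrix(tf), "duplicated")

  neg <- full
  neg$rate[5] <- -1
  write.table(neg, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_matrix(tf), "negative")
})

test_that("fold shifts scale exactly the named entries", {
  m <- build_uniform_matrix()
  expect_equal(apply_fold_shift(m, "TCC>T", 1)$rate, m$rate)

  m2 <- apply_fold_shift(m, "TCC>T", 2)
  expect_equal(m2$rate[m2$label == "TCC>T"], 2)
  expect_equal(sum(m2$rate != m$rate), 1)

  m09 <- apply_fold_shift(m, "TCC>T", 0.9)
  expect_equal(m09$rate[m09$label == "TCC>T"], 0.9)

  both <- apply_fold_shift(m, "TCC>T", 2, both_strands = TRUE)
  expect_equal(both$rate[both$label %in% c("TCC>T", "GGA>A")], c(2, 2))
  expect_equal(sum(both$rate != m$rate), 2)

  # fold then 1/fold recovers the original
  back <- apply_fold_shift(apply_fold_shift(m, "ACG>T", 1.7), "ACG>T", 1 / 1.7)
  expect_equal(back$rate, m$rate, tolerance = 1e-12)

  expect_error(apply_fold_shift(m, "TCC>T", 0), "positive")
  expect_error(apply_fold_shift(m, "TCC>C", 2), "valid mutation type")
})

test_that("normalization pins the sequence-averaged rate and is idempotent", {
  s <- generate_sequence(20002, seed = 5)
  shifted <- apply_fold_shift(build_uniform_matrix(), "TCC>T", 2)
  norm <- normalize_overall_rate(shifted, s, 1e-8)
  expect_true(mutspectra:::is_normalized(norm))

  # independent oracle: direct per-site summation over the interior
  pos <- 2:(seq_length(s) - 1)
  totals <- brute_site_totals(s, pos, norm)
  expect_equal(mean(totals), 1e-8, tolerance = 1e-10)
  # TCC sites mutate faster than non-TCC sites after the shift
  trips <- substr(vapply(pos, function(p) substr(s$bases, p - 1, p + 1),
                         character(1)), 1, 3)
  expect_gt(mean(totals[trips == "TCC"]), mean(totals[trips != "TCC"]))

  again <- normalize_overall_rate(norm, s, 1e-8)
  expect_equal(again$rate, norm$rate, tolerance = 1e-12)

  zero <- normalize_overall_rate(build_uniform_matrix(), s, 0)
  expect_true(all(zero$rate == 0))
  expect_error(normalize_overall_rate(zero, s, 1e-8), "all-zero")
})

test_that("site_rate returns the triplet total and conditional distribution", {
  s <- ancestral_sequence("ATCCGA")
  m <- apply_fold_shift(build_uniform_matrix(), "TCC>T", 2)
  m <- normalize_overall_rate(m, s, 1e-8)
  sr <- site_rate(s, 3, m)  # triplet TCC centred at position 3
  expect_equal(sr$triplet, "TCC")
  expect_equal(unname(sr$conditional["T"]), 0.5)  # 2 / (2 + 1 + 1)
  expect_equal(unname(sr$conditional[c("A", "G")]), c(0.25, 0.25))
  expect_error(site_rate(s, 1, m), "interior")
  expect_error(site_rate(s, 6, m), "interior")
})

test_that("summed site rates equal interior length x overall rate", {
  s <- generate_sequence(5002, seed = 6)
  m <- normalize_overall_rate(
    apply_fold_shift(build_uniform_matrix(), "AAA>T", 3), s, 2e-8)
  totals <- brute_site_totals(s, 2:(seq_length(s) - 1), m)
  expect_equal(sum(totals), 5000 * 2e-8, tolerance = 1e-10)
})
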