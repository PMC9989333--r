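# Shared fixture builders (everything is generated in code; no binary files).

# Single constant-size population: the simplest coalescent test bed.
one_pop_model <- function(n = 1000) {
  population_model(list(pop = list(epoch(0, n))))
}

# Two isolated populations joined by a split: used for privacy/structure tests.
two_pop_model <- function(n1 = 1000, n2 = 1000, split = 2000) {
  population_model(
    populations = list(A = list(epoch(0, n1)), B = list(epoch(0, n2))),
    splits = list(split_event(split, "B", "A"))
  )
}

# Uniform-composition sequence + normalized Jukes-Cantor matrix, sized for
# quick simulation (higher-than-biological rate keeps runtimes short without
# changing any of the laws under test).
quick_world <- function(len = 20002, rate = 1e-6, seed = 42) {
  seq <- generate_sequence(len, seed = seed)
  mat <- normalize_overall_rate(build_uniform_matrix(), seq, rate)
  list(seq = seq, mat = mat)
}

shipped_model <- function(name) {
  load_model(system.file(file.path("extdata/models", name),
                         package = "mutspectra"))
}

# Independent brute-force per-site total mutation rate: direct lookup of the
# three matrix entries for the substring around each position.
brute_site_totals <- function(seq, positions, mat) {
  vapply(positions, function(p) {
    trip <- substr(seq$bases, p - 1L, p + 1L)
    sum(mat$rate[mat$triplet == trip])
  }, numeric(1))
}
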