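---
title: "Simulating sample-size and demography effects on mutational spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sample-size and demography effects on mutational spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutspectra)
```

## The problem

The trinucleotide mutational spectrum of a population — the distribution of
its segregating variants over the 192 (ancestral triplet, derived base)
categories, or 96 after merging reverse-complement pairs — is a workhorse
statistic for detecting evolution of the mutation process itself. Comparative
analyses typically contrast the spectra of *population-private* SNPs: sites
segregating in the focal population while every other population carries only
the ancestral allele. Two practical questions precede any such analysis:

1. How many individuals must be sampled before the subsampled spectrum
   faithfully represents the whole population's spectrum?
2. Given realistic sample sizes, how large a rate shift of a single mutation
   type (for example TCC>T, the 5'-TCC-3' to 5'-TTC-3' change) can a
   two-proportion test detect at a given genomic scale?

Both answers depend on demographic history, because history controls how many
private variants a sample of *n* individuals yields. This package provides a
simulation framework to compute these answers before data collection.

## The simulation model

**Demography.** A `population_model` is a set of populations with
piecewise-exponential diploid size trajectories, joined backward in time by
split events, with optional migration. `N` counts diploid individuals; a pair
of lineages in a population of current size `N(t)` coalesces at rate
`1/(2N(t))` per generation. An epoch declares the size at its most recent
boundary and a forward growth rate `r`, so `t` generations into the epoch
(backward) the size is `N exp(-r t)`; the waiting time to coalescence under
exponential size change is drawn by exact inversion of the cumulative hazard.
Migration is parameterized forward in time — `rate` is the fraction of the
destination replaced by immigrants per generation — and realized backward as
per-lineage relocation at the same rate; `migrants` entries (`M` diploid
immigrants per generation) are converted as `m = M/(2N_dest)`.

**Engine choice.** The experiments the package packages were originally
cluster-scale forward simulations. Under neutrality the backward-in-time
structured coalescent generates samples from the same distribution at a small
fraction of the cost, so the production engine (`simulate_genealogy()`) is a
structured coalescent. Because that equivalence is the package's central
modelling bet, a deliberately naive forward Wright–Fisher simulator
(`forward_wf_oracle()`, guarded to `N <= 500`, burn-in `10 Ne` generations)
ships alongside it, and the test suite checks that the two engines agree on
segregating-site counts, alongside closed-form checks (`E[T2] = 2N`,
Watterson's expected number of segregating sites, the neutral folded
site-frequency spectrum, and expected branch lengths `E[L_k] = 4N/k`).

**Mutation.** Rates are context-specific: a 192-entry matrix assigns each
(ancestral triplet, derived base) a per-site per-generation rate.
`normalize_overall_rate()` rescales a matrix so the *sequence-averaged* total
per-site rate equals a target (default `1e-8` per bp per generation, the
conventional hominoid value); relative context effects are preserved.
Mutations are dropped on the genealogy as a Poisson process: per branch and
site, mean = branch length x site rate, with the derived base drawn from the
site's conditional distribution. Contexts are always the *ancestral*
triplets, and any site struck more than once anywhere on the genealogy is
discarded — the analysis is restricted to biallelic SNPs, so multi-hit sites
are unobservable rather than re-thrown. Population-specific mutation models
(the fine-scale fold shifts) are honoured through per-branch population
occupancy: each branch segment mutates at the rate of the population the
lineage occupied at that time.

**Recombination.** A constant crossover rate is approximated by partitioning
the sequence into independent non-recombining windows (default 10 kb,
`window_length`). This overstates recombination between windows and ignores
it within them; spectrum *means* are unaffected (mutation types are assigned
independently per mutation), while variances across windows are approximate.
A full ancestral-recombination-graph would add cost without changing the
statistics this package reports.

## The synthetic sequence generator

Real reference chromosomes enter the original analyses only through their
base composition (triplet availability). `generate_sequence()` therefore
draws i.i.d. bases with a configurable composition — uniform by default, or
e.g. `c(A = .295, C = .205, G = .205, T = .295)` for a human-like 41% GC. It
does **not** emulate CpG depletion, isochores, repeats, or missing-data
structure; `impute_missing()` handles the N-site imputation step (draws from
the chromosome-wide composition, once per experiment) that real assemblies
need. A green test on synthetic sequence therefore establishes the
statistical machinery, not robustness to real-genome context heterogeneity.
Uniform composition is the default for the fine-scale experiments because the
power baseline assumes every category is equally likely (expected proportion
`1/c`); with skewed compositions the realized baseline deviates from `1/c`
in proportion to the triplet-frequency skew.

## Broad-scale experiment: spectrum convergence

For each chromosome replicate the whole-population stand-in (a large sample,
default 50-100 diploids per population; the published runs used the entire
simulated population) is subsampled *with replacement* at a grid of sizes —
`default_scheme()` is the published grid: 5-200 by 5, 300-1,000 by 100,
2,000-10,000 by 1,000, five replicates each — and each subsampled private
spectrum is compared with the full-sample private spectrum by the **total
difference**: the sum over categories of absolute proportion differences
(twice the total variation distance; signed differences cancel identically,
which is why the absolute value is the meaningful reading). Results are
reported both on the raw [0, 2] scale and as percentages.

Because mutation types are assigned independently per mutation, the
subsampled spectrum is multinomial given its private-SNP count, and the
expected total difference scales like the number of categories times
`sqrt(2 p (1-p) / (pi S))` with `S` the subsample's private-variant count.
Demography enters through `S`: histories that depress private variation at a
given sample size (size declines, out-of-Africa-style bottlenecks, high
inbound migration — which converts private variants into shared ones)
converge more slowly. The shipped human model reproduces this: the European
population (bottleneck followed by growth) shows roughly twice the total
difference of the African population at matched sizes. Among the three basic
models (ancestral size 10,000; derived population constant at 10,000,
declined to 1,000, or grown to 100,000), the decline model converges slowest
and the growth model marginally fastest — instantaneous growth *increases*
subsample private-variant counts, so by itself it does not slow convergence;
it is the bottleneck component of real expansions that does.

## Fine-scale experiment: power for a single-type shift

Regions (default 1 Mb, 100 per scenario in the published setting; configurable)
are simulated under a Jukes–Cantor matrix, with the focal type's rate — and,
strand-symmetrically, its reverse complement's — multiplied by a fold `f`
(published range 0.9-2.0) in exactly one population of the compared pair,
then renormalized so the overall rate stays at `1e-8`. Each population's
private segregating variants give a binomial count: trials = private SNPs,
successes = those of the focal type. The two-proportion statistic is

    Z = (p2 - p1) / sqrt(p* (1 - p*) (1/n1 + 1/n2)),   p* = (n1 p1 + n2 p2) / (n1 + n2)

with `n` the trial counts. Since the shifted population is unknown in real
data, both scenarios (shift in population 1; shift in population 2) are
simulated, powers are averaged across region replicates within scenario, and
`report_min_power()` reports the minimum of the two scenario averages.

Three power modes are provided. The default (`"analytic"`) evaluates the
normal-approximation power at the model-expected proportions — `1/c` for the
null population and `f/(c-1+f)` for the shifted one, `c = 96` by default —
using each replicate's *realized* trial counts; it is exactly
alpha-calibrated at `f = 1` and isolates the demographic signal (trial
counts) from binomial noise. `"rejection"` is the Monte-Carlo cross-check:
the Z test is run on the realized counts and power is the rejection rate.
`"analytic_realized"` plugs the realized proportions into the analytic
formula. Alpha defaults to 0.05 two-tailed (the test is two-tailed by
specification; the level itself was an open choice and is recorded in every
output row).

## Numerical and design choices

* **Diploid convention** throughout: `N` is diploid individuals, coalescence
  rate `1/(2N)`, subsampling operates on individuals (= 2 haplotypes).
* **Split-to-sampling interval of the basic models**: not fixed by the
  published description; default 4,000 generations (long enough for private
  variation to accumulate, short relative to `Ne`), overridable via
  `build_basic_model(split_time =)`.
* **Privacy under subsampling** is evaluated against the *full* samples of
  the non-focal populations (only the focal population is subsampled); all
  derived-allele frequencies including singletons enter the spectrum, since
  simulated data carry no genotyping error.
* **96-category convention**: reverse-complement pairs are merged onto the
  pyrimidine-centred representative (middle ancestral base C or T), the
  dominant convention in mutational-signature work. Matrices always live in
  the stranded 192 space; collapse happens at reporting.
* **Fold shifts and renormalization**: `apply_fold_shift()` scales exactly
  the named entry (and optionally its reverse complement); holding the
  genome-wide average rate fixed afterwards is a separate, explicit
  `normalize_overall_rate()` call, so sensitivity analyses can skip it.
* **Degenerate inputs**: empty spectra are flagged and excluded from
  distance computations; a pooled proportion of 0 or 1 makes `Z` undefined
  (error in `z_statistic()`, counted as non-rejection in the Monte-Carlo
  power mode); all-N sequences cannot be imputed; matrices must contain
  exactly the 192 types, once each, with non-negative rates.
* **Seeding**: every experiment cell derives an independent stream via
  `seed_stream()` (FNV-1a hash of the master seed and a label path), so
  results are reproducible cell-by-cell and independent of evaluation order.
* **Shipped demographies**: the human three-population out-of-Africa
  configuration uses the published maximum-likelihood parameter set it cites
  in its provenance block (generation time 25 y). The chimpanzee
  four-subspecies configuration is an *approximate reconstruction* — the
  exact published estimates live in a supplement that was not available —
  constrained by the quoted present-day sizes (about 5,700 Western; about
  72,000 Central), the accepted split topology and time scale, published
  diversity levels, and high Eastern-involved migration (generation time
  20 y); its filename carries a `_synthetic` suffix and its parameters were
  fixed once, before any acceptance measurement.

## Limitations

* Neutrality is assumed everywhere; selection, gene conversion, and indels
  are out of scope.
* The window approximation misstates linkage: between-window independence is
  too strong, within-window linkage too strong in the other direction.
* The forward oracle deliberately supports only constant-size, no-migration
  histories at small `N`; it is a validation tool, not a simulator.
* Synthetic sequences reproduce base composition only; fine-scale landscape
  features of real chromosomes (CpG islands, repeats) are not emulated.
* The chimpanzee configuration is a labelled stand-in, adequate for
  method-level conclusions (power scales, convergence ordering) but not for
  parameter-exact replication.

## A worked call sequence

```{r example, eval = FALSE}
chimp <- load_model(system.file("extdata/models/chimpanzee_four_pop_synthetic.json",
                                package = "mutspectra"))
surf <- power_surface(chimp, c("Central", "Western"),
                      folds = c(1, 1.725, 2), sizes = c(4, 10),
                      region_length = 1e6, replicates = 5, seed = 1)
report_min_power(surf)
```
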