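Package: mutspectra
Title: Simulation-Based Power and Sampling Analysis of Trinucleotide
    Mutational Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how sample size and demographic history shape
    observed trinucleotide mutational spectra and the power to detect
    population-specific shifts of single mutation types. Provides a
    structured-coalescent simulator with population splits, exponential
    growth and migration; context-dependent (192-type) mutation rate
    matrices; extraction of population-private biallelic SNPs and their
    192- or 96-category spectra; subsampling-with-replacement convergence
    experiments; and a two-proportion Z-test power procedure for
    single-mutation-type rate shifts. A small forward Wright-Fisher
    simulator is included as an independent cross-check of the coalescent
    engine. Shipped demographic configurations cover human
    (African/European/East Asian) and chimpanzee (four subspecies)
    population histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
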