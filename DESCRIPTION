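Package: pennaXY
Title: Forward-Time Penna Simulation of Sex Chromosome Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based forward-time simulator of sex chromosome
    evolution built on the sexual Penna bit-string ageing model. Diploid
    individuals with bit-string chromosomes live on a toroidal lattice;
    loci activate chronologically with age and accumulated homozygous
    recessive defects beyond a threshold are lethal. Recombination between
    the X and Y in males can be switched off, fixed at the X-X rate, or
    left to evolve through a heritable father-to-son modifier, and mating
    is either promiscuous or lifelong monogamous. The package computes the
    readouts used to study Y chromosome degeneration and Muller's ratchet:
    per-locus defect profiles, cohort X/10, Y/X and male/female ratios,
    degeneration-rate slopes, recombination suppression times, and the
    Jukes-Cantor divergence correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
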