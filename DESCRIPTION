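Package: nrrsim
Title: Neutral Forward-Time Simulation of Recombination Loss on Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of a proto-sex chromosome in
    which heterozygosity adjacent to the sex-determining (SD) locus suppresses
    local recombination, so that a non-recombining region (NRR) can arise and
    expand around the SD locus by purely neutral processes.  Per-meiosis
    recombination probabilities are reduced in proportion to the number of
    heterozygous sites in a sliding window; no selection of any kind is
    modelled.  The package provides parameter validation with population-scaled
    rates (theta = 4N*mu, rho = 4N*r), uniform, heterochiasmatic and
    hotspot/coldspot ancestral recombination landscapes, male mutation bias
    with a constant sex-averaged rate, summary statistics (NRR size, dXX, dXY,
    male-female FST profiles, pairwise diversity), replicate averaging,
    parameter-sweep presets, brute-force oracles for testing, figure helpers
    and a command-line interface.  The generation loop is implemented in C++
    via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
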