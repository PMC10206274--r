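Package: ocsim
Title: Stochastic Simulation of Intense Layer Breeding Programmes with
    Genomic and Optimal Contribution Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of a closed-nucleus layer
    chicken breeding programme. Generates base-population haplotypes under a
    piecewise-constant coalescent demography, simulates three correlated
    additive egg-production traits, and runs multi-year breeding scenarios
    that compare conventional truncation selection (pedigree BLUP), genomic
    truncation selection (single-step GBLUP), minimum-progeny-inbreeding
    mate allocation, and genomic optimal contribution selection along a
    trigonometric-penalty frontier. Reports genetic gain, genic variance,
    conversion efficiency, rates of inbreeding, effective population size,
    and accuracy of selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
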