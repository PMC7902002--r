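Package: icbreedsim
Title: Stochastic Simulation of Intercrop Breeding Programs with Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates long-term intercrop breeding for two component crops and
    compares a phenotypic-selection program against four genomic-selection
    program designs (Baseline-GS, PYT-GS, DH-GS and Grid-GS) at equal annual
    operating cost. Founder haplotypes are generated under a coalescent model
    with a piecewise-linear effective-population-size history; monocrop and
    intercrop grain yield are simulated as correlated additive traits;
    general intercropping ability is predicted with multivariate and
    two-crop ridge-regression (RR-BLUP) mixed models with heterogeneous
    residual variances; and program designs are compared by genetic gain,
    genetic variance and prediction accuracy using paired log-ratio
    statistics over simulation replicates. Includes a cost engine that
    reconciles per-stage plot, doubled-haploid and genotyping costs across
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
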