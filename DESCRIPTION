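Package: trafficlines
Title: Genetic Calculus for Fluorescent Seed-Marker Traffic Lines
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for working with Arabidopsis thaliana "traffic lines":
    stocks carrying a pair of linked seed-expressed eGFP and DsRed transgenes
    in cis on one chromosome. Ships a validated catalog of 162 short-interval
    lines with genome-interval queries and integrity checks, estimates
    recombination fractions and map distances from fluorescence-classed
    testcross seed counts, computes exact gamete and seed-class probability
    distributions for the crossing schemes these lines support (seed
    genotyping by fluorescence dosage, mapping, balancer purity, transgene
    rescue of lethal mutations, separation of tightly linked mutations), and
    simulates meiosis with crossover interference as a stochastic oracle and
    synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
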