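Package: asmram
Title: Assembler Peak-RAM Prediction and Sewage Core-Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("asmram", "developers", email = "asmram@example.org", role = c("aut", "cre"))
Description: Predicts the peak RAM consumption of a metagenome assembler from
    k-mer-spectrum features of the input read set, turns predictions into cloud
    VM flavor requests with retry-on-out-of-memory accounting, and implements a
    ubiquity-based core-microbiome analysis for globally sampled sewage
    metagenomes. Includes exact canonical k-mer counting, a correlation
    screening / cross-validation / grid-search / bias-calibration model
    pipeline built on extremely randomized trees, fleet allocation policy
    simulation, and seeded synthetic-data generators (genomes, read sets,
    training tables with a planted RAM response, abundance tables with planted
    core species) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    ShortRead
Config/testthat/edition: 3
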