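Package: halofba
Title: Constraint-Based Analysis of Halophile Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of genome-scale metabolic
    reconstructions of halophilic bacteria. Provides an in-memory model
    representation with stoichiometric matrix construction, a TSV/JSON model
    dialect with round-trip input/output, reconstruction quality control
    (dead-end metabolite detection, elemental mass and charge balancing,
    adjacency/topology and network statistics, cross-model reaction
    comparison), flux balance analysis and flux variability analysis on a
    built-in bounded-variable simplex solver, substrate-utilization phenotype
    screens, and osmoadaptation case studies for the choline-betaine and
    ectoine biosynthesis pathways. A synthetic-network generator supplies
    analytic toy models, randomized quality-control networks with recorded
    ground truth, and a curated mini-halophile fixture so the entire pipeline
    runs offline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
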