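Package: trifold
Title: Protein Structure Prediction on the 2D Triangular-Lattice HP Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hydrophobic-polar (HP) lattice protein folding on the
    two-dimensional triangular lattice. Provides the lattice geometry and
    contact free-energy function, a genetic algorithm with an elite-based
    reproduction strategy (ERS-GA), a hybrid of hill climbing and the GA
    (HHGA) with two local-search operators, an exhaustive-enumeration
    oracle for short chains, and a registry of the eight standard benchmark
    sequences with a multi-run experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
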