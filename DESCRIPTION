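Package: smirfit
Title: Desk-Scale SMIRKS-Typed Force-Field Fitting and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for building and validating small-molecule
    force fields typed by SMIRKS patterns (direct chemical perception).
    Provides an ordered SMIRKS-keyed parameter container with XML/JSON
    round-trip serialization, last-match-wins parameter assignment, a gas-phase
    molecular-mechanics engine with analytic gradients, constrained
    minimization and restrained torsion scans, regularized least-squares
    fitting objectives for valence parameters (internal-coordinate and
    weighted torsion-profile targets) and Lennard-Jones parameters (densities
    and enthalpies of mixing through a pluggable property backend), the
    associated training-data curation filters, conformer benchmark statistics
    (RMSD, TFD, relative conformer energy errors), free-energy benchmark
    statistics with bootstrap confidence intervals, and a synthetic-data
    generator with known ground truth for end-to-end parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    igraph,
    yaml,
    ChemmineR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
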