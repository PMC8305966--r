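Package: comtop
Title: Consensus Protein Residue-Residue Contact Prediction by Mixed
    Integer Linear Optimization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns per-method weights for combining the confidence scores
    of several protein residue-residue contact predictors by solving a
    mixed integer linear program that maximizes the number of correctly
    discriminated residue pairs, then scores, ranks and evaluates consensus
    contact predictions.  Includes readers and writers for CASP RR contact
    files and pair-list truth files, native contact map extraction from PDB
    structures, the standard top-kL evaluation metrics (accuracy, coverage,
    specificity, NPV, MCC), Jaccard method-overlap matrices, Bland-Altman
    agreement analysis, and a synthetic corpus generator with controllable
    predictor reliability and inter-method overlap.  The optimization core
    (a dense two-phase simplex solver, an exact cutting-plane solve of the
    soft-margin formulation and branch-and-bound for the literal
    formulation) is self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
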