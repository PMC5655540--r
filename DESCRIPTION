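Package: ssmenrich
Title: Site-Saturation Mutagenesis Library Design and Selection Enrichment
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for engineering and affinity-maturing designed
    small-molecule binders. Covers the sequence side of the workflow --
    NNK site-saturation mutagenesis (SSM) library enumeration and primer
    design, paired-end read merging with Phred quality filters,
    single-mutant variant counting, and masked log2 enrichment statistics
    with heat-map output -- together with the structural side: hydrated
    ligand preparation (explicit water placement at idealized geometry),
    rotatable-bond counting, design-pose filter cascades, and
    Shrake-Rupley buried surface area (dSASA). A synthetic-data module
    simulates SSM libraries, multi-round selection with known per-variant
    fitness, and MiSeq-like paired-end reads so the whole pipeline can be
    validated against ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
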