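Package: ican
Title: Interpretable Carbon-Based Array of Neighborhoods Molecular Encoding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the iCAN (interpretable Carbon-based Array of
    Neighborhoods) molecular encoding: a deterministic, interpretable
    fingerprint that records element frequencies in the multi-level
    graph neighborhoods of every backbone carbon of an organic molecule.
    Peptides (FASTA) are converted to SMILES by N-to-C condensation of
    residue fragments, molecules are parsed into labeled graphs with
    explicit hydrogens, carbon chains are indexed by a deterministic
    depth-first traversal with ring opening, and per-carbon neighborhood
    element counts are assembled into counting arrays, flattened and
    zero-padded into fixed-length feature matrices. Includes grayscale
    image and relevance heat-map representations, a seeded random-forest
    classification harness (repeated stratified cross-validation, binary
    F1, impurity-based feature importances, Mann-Whitney U comparison of
    score distributions), and synthetic-data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    png,
    ranger,
    Biostrings,
    ChemmineOB,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
biocViews: Software, Cheminformatics, Classification, FeatureExtraction,
    Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
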