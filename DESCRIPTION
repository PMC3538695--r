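Package: barcodeval
Title: Evaluation of Multi-Marker DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate multi-marker DNA barcode reference libraries
    for local floras, in the style of the rbcL + matK + ITS2 libraries built
    for northern vascular plants. Reads per-marker alignments and specimen
    metadata, builds concatenated supermatrices with configurable
    specimen-inclusion rules, computes within-family mean pairwise distances
    (p-distance and K2P) with cross-marker correlations, infers maximum
    parsimony trees with a seeded parsimony-ratchet search and strict
    consensus, scores species resolution by the joint
    monophyly-plus-diagnostic-character criterion, and flags pseudogenes
    (frameshifts and internal stop codons), ITS2 paralogy, contamination and
    specimen misidentification. A seeded Jukes-Cantor library simulator with
    planted anomalies and ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
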