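Package: ncanet
Title: Dynamic Transcriptional Regulatory Networks by Network Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs stage-resolved transcriptional regulatory networks from
    developmental time-course expression data. Builds a coexpression-derived prior
    connectivity matrix (Pearson correlation plus a hierarchical-clustering sub-tree
    rule), checks and enforces the identifiability criteria of network component
    analysis, estimates hidden transcription-factor activities and control strengths
    by constrained alternating least squares, assembles a signed stage-annotated
    regulatory digraph, and censuses its over-represented motifs (sizes 3-5) against
    a degree-preserving random ensemble. Includes a seeded synthetic-data generator
    with known ground truth so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    Matrix,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
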