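Package: acst
Title: Analysis of Consistent Signal Transduction in Signaling Pathways
Version: 0.1.0
Authors@R:
    person("ACST", "Maintainers", email = "acst@example.org", role = c("aut", "cre"))
Description: Topology-aware test for deregulation of signaling pathways from
    two-group gene expression data. Each pathway is modeled as a directed graph
    of genes with signed transcription-factor/target (gene-expression) edges;
    sign-consistent cascades are extracted as maximal consistent subgraphs,
    scored by standardized squared Welch t statistics weighted by directed
    distance to the pathway's terminal effectors, and assessed with a
    subject-sampling class-label permutation null and a resampling-based false
    discovery rate point estimator. Includes a KGML (KEGG Markup Language)
    reader restricted to gene-expression relations, a plain signed edge-list
    dialect, synthetic pathway and expression generators with planted
    consistent cascades, a brute-force oracle for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
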