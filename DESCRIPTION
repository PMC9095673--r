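Package: degronon
Title: Degron Masking and Co-Degradation Module Analysis for Protein
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how protein-protein interactions occlude
    degradation signals (degrons) and coordinate protein turnover.
    Maps partner binding sites and short linear motifs onto tripartite
    degrons (E3-recruiting motifs, ubiquitination sites, disordered
    proteasome-engagement regions), quantifies binding competition from
    proteome-wide abundance data using an equally-populated rank-bin
    scheme, implements the Wang graph-based Gene Ontology semantic
    similarity measure over Biological Process annotations, and mines
    interaction networks for co-degrading, functionally coherent modules
    ("degronons") via degree-preserving network randomization, half-life
    ratio statistics and shortest-path analysis. Includes seeded
    synthetic-data generators that emulate every input format with known
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
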