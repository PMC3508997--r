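Package: tandemdup
Title: Detection and Characterisation of Co-Localised Duplicated Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies groups of tandem (co-localised) duplicated genes on a
    genome from peptide sequences and gene coordinates, using a weighted
    protein sequence identity with a length-dependent twilight-zone threshold,
    a gene-rank window with closest-downstream linking, and transitive-closure
    grouping.  Detected groups are characterised by the proportion of
    significant pairwise expression correlations across expression datasets
    and by graph-based (Wang) semantic similarity of Gene Ontology
    annotations, with co-localised non-duplicated and random control groups
    for comparison.  A synthetic-fixture generator produces genomes with
    planted duplicate families, expression matrices with planted correlation,
    and toy ontologies, so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
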