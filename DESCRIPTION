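Package: litgonet
Title: Gene-Gene Association Networks from Gene Ontology Guided Literature Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers functional associations among human genes from the
    co-occurrence of gene names and Gene Ontology (GO) terms in literature
    abstracts. Gene-GO association strength is measured by an upper-tail
    hypergeometric test with a mid-p continuity correction; gene-gene
    similarity is the cosine between truncated negative-log-p association
    profiles; thresholding the similarities yields weighted association
    networks whose communities are detected by seeded asynchronous label
    propagation and annotated by mean-p GO enrichment. Includes a
    co-occurrence-only baseline for method comparison, a synthetic corpus
    simulator with planted functional modules for offline validation, TSV
    and GraphML import/export, and a command-line interface covering the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    data.table,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
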