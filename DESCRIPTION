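Package: mirlink
Title: Context-Specific miRNA-mRNA Interaction Discovery from Paired
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate microRNA-target interactions in a given
    biological context by combining one-sided negative-correlation testing
    across all miRNA-mRNA pairs of a paired expression dataset with
    sequence-based target prediction databases. Provides two-group
    differential expression (t, Wilcoxon, moderated-t, rank product) used as
    annotation, Benjamini-Hochberg control over the full pair family,
    interaction scoring, Cytoscape SIF network export, hypergeometric
    gene-set over-representation, multi-dataset comparison of interactomes
    (shared/specific interactions, k-means on correlation profiles,
    hierarchical clustering and PCA of datasets), and a synthetic paired-data
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
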