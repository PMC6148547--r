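Package: mirkey
Title: Key-Gene and Crucial-Pathway Prioritization for a miRNA from
    Expression, Interaction and Pathway Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico cascade that prioritizes the key target genes and
    crucial pathways of a microRNA from five evidence layers: case/control
    expression studies of the miRNA (standardized-mean-difference
    meta-analysis with heterogeneity, publication-bias, sensitivity,
    influence and subgroup analyses), tumor-versus-normal gene expression
    (differential-expression screening), multi-database target-prediction
    votes, a confidence-weighted protein-protein interaction network
    (topological centrality consensus), and pathway gene sets (hypergeometric
    enrichment, Jaccard/overlap crosstalk, MCODE clustering, bipartite
    gene-pathway cores, median-rank multi-study meta-analysis with
    leave-one-out stability). A synthetic-data module generates every input
    with planted, recoverable ground truth, and a seed-site scanner locates
    7-mer matches to miRNA positions 2-8 on 3'UTRs with AU-richness and
    AU-rich-element classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    jsonlite,
    fgsea,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
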