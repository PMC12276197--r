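Package: hypercoex
Title: Hypergraph Co-Expression Analysis of Longitudinal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transcriptome-wide coordination across development by
    modelling co-expression as a hypergraph. Age-associated target genes are
    selected by variance filtering with a projection-score threshold, correlated
    against the rest of the transcriptome, and binarized at one standard
    deviation from the mean correlation to form a binary incidence matrix; its
    product with its transpose gives a reduced adjacency matrix of higher-order
    (shared-correlation) interactions. The package computes hypergraph
    connectivity and normalized Shannon entropy, peripheral complete-subgraph
    gene sets, permutation nulls, moving-window entropy time series, hypergraph
    random-walk transition matrices, per-pathway iterated entropy with Bayesian
    two-group comparison, normalized gene ranks with Fisher enrichment tests,
    and small closed-form phenotype statistics (delta-delta-Ct, Fulton's
    condition factor, respirometry summaries). A synthetic-data generator
    emulates a two-condition longitudinal study design with planted
    age-associated gene clusters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
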