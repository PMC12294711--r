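Package: priorank
Title: Seeded Candidate Gene Prioritization with Functional and Network
    Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate effector genes by integrating
    annotation-based functional similarity to a training (seed) gene set
    with topological proximity to the seeds on a protein-protein
    interaction network. Provides gene-set input/output (plain lists and
    GMT libraries), overlap and Jaccard analysis with a training/test
    partition, hypergeometric over-representation testing with
    Benjamini-Hochberg and Bonferroni correction, regulator enrichment
    with mean-rank aggregation across evidence libraries, fuzzy and
    Pearson similarity scoring combined by Fisher's inverse chi-square
    method, PageRank-with-priors and K-step Markov network scoring, and a
    linear integration of the scaled evidence into a final ranking. A
    synthetic-data generator produces fully specified benchmark bundles
    with planted effectors, regulators and enriched terms so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
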