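Package: mirlnclink
Title: Group-Preference Bayesian Ranking for miRNA-lncRNA Interaction
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts missing links in a bipartite miRNA-lncRNA
    interaction network with a group-preference Bayesian pairwise-ranking
    latent-factor model trained by stochastic gradient descent. Provides
    the three RNA-RNA similarity measures the model fuses (expression
    profile Pearson correlation, Needleman-Wunsch global sequence
    alignment, and local target-gene overlap indices: Common Neighbors,
    Adamic-Adar, Jaccard and Salton), a local per-miRNA ranking
    cross-validation protocol with AUC reporting, an observed-versus-
    unobserved cluster correlation analysis, and a planted-block
    synthetic data generator for end-to-end testing without database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
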