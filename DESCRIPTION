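Package: cgcoupling
Title: Dissecting Coupling Between Regional Gene Co-Expression and Brain
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics and inference for relating regional transcriptomic
    similarity to resting-state functional connectivity. Implements
    correlated gene expression (CGE), connectivity-expression coupling (CEC)
    and per-gene per-connection coupling contributions; individual-level
    screening of connectivity-related genes with Bonferroni correction and a
    prevalence filter; semi-nonnegative canonical polyadic (CP) decomposition
    of the gene x connection x individual coupling tensor with
    permutation-based gene selection; and network-level dissection of
    network-shared versus network-specific genes, including an adapted
    specificity index. A synthetic-data generator with planted coupling
    genes, network structure and homologous connections provides ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
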