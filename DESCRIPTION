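Package: splicefun
Title: Splice-Function Networks from Protein Keyword Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Projects transcriptional units (TUs) and their alternative
    splice variants onto the functional space of the proteome. Unique
    combinations of protein annotation keywords become functional labels
    (FLs); TUs are classified as monoform or polyform by the diversity of
    the FLs their isoforms carry; candidate functional switches are
    detected by Jaccard comparison of keyword sets; the three
    transcript-protein-function relation histograms are summarized and
    fitted with a two-component mixture of an exponential body and a
    generalized discrete Pareto tail; weighted splice-function networks
    (SFNs) on FL nodes are built from polyform TUs and parameterized; and
    keyword over-representation in TU groups is scored by a hypergeometric
    test with a modified Bonferroni correction. A synthetic-data generator
    emulates the statistical structure of curated isoform-protein sets so
    the whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    Matrix,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
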