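Package: mirlit
Title: Text Mining of miRNA Literature with Topic Models and Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for mining microRNA (miRNA) literature:
    reading and filtering MEDLINE and PubTator corpora, regex-based miRNA
    mention recognition and nomenclature normalization, Latent Dirichlet
    Allocation topic modeling with topic-year and topic-miRNA association
    matrices, balanced binary document classification (Naive Bayes, decision
    tree, random forest, support vector machine) with full metric reporting
    and permutation feature importance, gene co-mention matrices with
    target-list intersection, and local hypergeometric over-representation
    analysis over GMT gene-set collections. A synthetic corpus generator with
    planted topics, class-conditional miRNA frequencies, and realistic surface
    form variation makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    stats,
    utils,
    e1071,
    rpart,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
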