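Package: opinionminer
Title: Topic Modeling and Multidimensional Sentiment Analysis of Short
    Social-Media Texts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for mining public opinion from short
    social-media documents (microblog comments). Provides lexicon-based
    multidimensional emotion scoring over a seven-category emotion taxonomy,
    biterm and latent Dirichlet allocation topic models fitted by collapsed
    Gibbs sampling with perplexity-driven selection of the topic count,
    TF-IDF featurization with sparse logistic-regression and multinomial
    naive-Bayes sentiment classifiers, and spatiotemporal aggregation of
    sentiment by pandemic stage and administrative region with natural-breaks
    classification and a permutation test of regional similarity. A synthetic
    microblog-corpus generator with full ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
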