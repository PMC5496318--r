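Package: gaknn
Title: Ensemble Gene Selection and Multi-Class Tumor Classification with
    GA/KNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for multi-class classification of
    RNA-seq gene expression profiles. A genetic algorithm searches over
    fixed-size gene subsets ("chromosomes") scored by leave-one-out
    k-nearest-neighbour training accuracy with a reject option; repeating
    the search many times over a fixed train/test partition yields
    per-sample prediction profiles (the proportion of runs assigning each
    sample to each class, pi_cc for the true class), modal prediction
    accuracies, and frequency-based gene importance ranks. Also provides
    silhouette-guided k-means subtype discovery, hypergeometric gene-class
    enrichment, cohort rank-list comparison, exact Wilcoxon rank-sum tests,
    proportion-matched cohort subsampling, and a synthetic expression-data
    generator with planted discriminative genes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
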