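Package: litscape
Title: Topic-Model Landscapes of Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for mapping the thematic
    landscape of a corpus of scientific abstracts. From a time-stamped JSONL
    corpus it performs deduplication, tokenization with Porter stemming and
    frequency-based vocabulary pruning, fits latent Dirichlet allocation by
    collapsed Gibbs sampling with c_v coherence model selection, and derives
    the downstream statistics used in literature-mining studies of research
    fields: topic-weighted TF-IDF vocabularies, yearly topic proportions and
    Shannon-entropy diversity, topic co-occurrence, lexicon-based sentiment,
    a TF-IDF/PCA/Leiden document landscape with differential cluster words,
    topic enrichment, temporal cluster evolution, thematic-stability trends,
    hallmark-stem presence, and semantic-overlap gap discovery. A synthetic
    Dirichlet-multinomial corpus generator with planted temporal trends,
    clusters, marker stems, and duplicates provides ground truth so every
    stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
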