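Package: habscore
Title: Habitat Preference Scoring of 16S rRNA Sequences and Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Habitat-based analysis of prokaryotic 16S rRNA gene sequences and
    community profiles. Builds habitat-labeled reference sequence databases with
    per-project subsampling, finds similarity hits with a k-mer seeded
    affine-gap local aligner (or imports BLAST tabular hits), converts hits into
    compositional habitat preference scores for single sequences and for
    abundance-weighted communities, runs the associated downstream statistics
    (Mann-Whitney in-group versus out-group score tests, Spearman gradient
    correlations), and constructs an environment co-occurrence network from
    Bray-Curtis dissimilarities with pair-counting betweenness centrality.
    Includes a seeded synthetic-data generator producing reference databases,
    query sets, and gradient community studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
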