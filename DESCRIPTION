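Package: savae
Title: Similarity-Assisted Variational Autoencoders for Nonlinear
    Dimension Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonlinear dimension reduction of count and continuous data
    with an encoder/decoder structure. A variational autoencoder (VAE)
    is trained jointly with a UMAP-style fuzzy cross-entropy regularizer
    computed on expected low-dimensional similarities between variational
    posteriors, so the latent space inherits the grouping structure that
    neighbourhood-based methods recover while keeping a generative
    decoder. A two-stage conditional variant removes covariate (batch,
    donor) effects before similarity computation. Includes synthetic-data
    generators, Matrix Market count-matrix input/output, highly variable
    gene selection, negative-binomial/Gaussian/Bernoulli likelihoods, and
    clustering-based embedding evaluation (adjusted Rand index,
    normalized mutual information, k-means and DBSCAN with parameter
    search).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    methods,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    dplyr,
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
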