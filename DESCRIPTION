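Package: accessim
Title: Embedding-Based Simulation of Single-Cell Chromatin Accessibility Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates peak-by-cell count matrices of single-cell chromatin
    accessibility (scATAC-seq) data from low-dimensional cell- and peak-wise
    embeddings, with user-defined ground truths: discrete cell populations,
    continuous differentiation trajectories on a Newick tree, pseudo-real cell
    types, data batches, and cis-regulatory interaction hubs. A reference
    matrix supplies the target distributions of library size, cell non-zero
    proportion and peak summation (fitted by Gaussian mixtures, discrete
    long-tailed families, or kernel density estimation); Poisson (or
    Bernoulli) sampling from a corrected mean-parameter matrix yields
    synthetic counts that preserve those statistics. Evaluation metrics for
    comparing synthetic and real data (quantile comparisons, miLISI,
    clustering agreement, interaction-recovery F1) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    MASS,
    mclust,
    ape,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
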