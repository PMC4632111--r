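Package: camcr
Title: Cluster-Aided Multivariate Curve Resolution for NMR Metabolomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies reliable components in multivariate curve
    resolution-alternating least squares (MCR-ALS) analyses of binned 1D
    NMR spectra. Instead of fixing the number of components in advance,
    the factorization is repeated for every component number from one up
    to a maximum, all concentration profiles are pooled, and profiles that
    re-emerge reproducibly are found by average-linkage hierarchical
    clustering with multiscale-bootstrap approximately unbiased (AU)
    p-values. Clusters are accepted as reliable when they exceed a size
    threshold derived from randomly shuffled data and their internal
    pairwise correlation exceeds a cutoff, with recursive refinement of
    heterogeneous clusters. The package also provides the non-negativity
    constrained ALS engine with PCA-score initialization, spectral binning
    and normalization utilities, eight conventional number-of-components
    estimators for comparison, a synthetic mixture-spectrum generator with
    known ground truth, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'auclust.R'
    'camcr-package.R'
    'io.R'
    'mcr.R'
    'ncomp.R'
    'pipeline.R'
    'preprocess.R'
    'reliability.R'
    'summarize.R'
    'sweep.R'
    'synthetic.R'
    'utils.R'
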