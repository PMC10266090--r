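Package: rmtfc
Title: Random Matrix Theory Eigenfeatures for Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for summarizing voxelwise functional-connectivity matrices of
    4D BOLD fMRI images through the eigenvalues of the voxel correlation matrix
    and spectral observables from random matrix theory. Eigenvalues are computed
    efficiently through the transpose identity so cost scales with the number of
    volumes rather than the number of voxels. Provides eigenvalue trimming
    procedures, polynomial unfolding, the spectral rigidity and level number
    variance with Monte-Carlo convergence control, reference-ensemble simulators
    (Gaussian orthogonal ensemble, Poisson levels), a catalog of eigenvalue- and
    timeseries-based predictive features, and a multiverse evaluation harness
    that runs stratified five-fold cross-validated classification over a grid of
    analytic choices and summarizes distributions of fold-mean AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    class,
    e1071,
    randomForest,
    signal,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
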