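Package: cwas
Title: Connectome-Wide Association Analysis by Multivariate Distance Matrix Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise connectome-wide association analysis linking intrinsic
    functional connectivity to continuous phenotypes. Implements multivariate
    distance matrix regression (MDMR) with covariate-adjusted pseudo-F
    statistics and permutation inference, cluster-extent family-wise error
    correction by Gaussian random field theory and by permutation, post-hoc
    seed-based correlation analysis with group-level general linear models,
    dependent-correlation difference tests, behavioural cohort statistics,
    temporal preprocessing for resting-state BOLD data (nuisance regression,
    band-pass filtering, spatial smoothing), and a synthetic multi-subject
    data generator with planted connectivity-phenotype effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
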