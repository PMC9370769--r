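Package: sersnpc
Title: Label-Free Protein SERS Diagnostics for Nasopharyngeal Carcinoma Screening and Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of label-free blood-protein surface-enhanced
    Raman scattering (SERS) spectra for five-class cancer screening and staging
    (healthy controls plus nasopharyngeal carcinoma stages I-IV). Provides a
    synthetic cohort generator with 24 protein Raman bands, iterative improved
    modified polynomial (I-ModPoly) fluorescence background subtraction, area
    normalization, nonparametric peak-intensity statistics (Mann-Whitney U,
    Kruskal-Wallis), a one-dimensional convolutional neural network classifier
    trained by backpropagation with Adam, and a PCA-LDA chemometric comparator,
    orchestrated by a seeded end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
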