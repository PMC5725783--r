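Package: opselect
Title: Selection Inference and Spectral Tuning Prediction for Visual Opsin Genes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of selective pressure on protein-coding
    genes with codon substitution models (branch, site and branch-site dN/dS
    models compared by likelihood-ratio tests and BIC, with empirical-Bayes
    detection of positively selected sites), together with rule-based prediction
    of visual-pigment absorption peaks (lambda-max) from amino acids at canonical
    spectral tuning sites in bovine rhodopsin numbering. Includes a phylogenetic
    codon-sequence simulator with branch- and site-heterogeneous omega for
    calibration and parameter-recovery experiments, motivated by comparative
    studies of snake visual opsins (LWS, RH1, SWS1).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
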