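Package: amyforest
Title: Random-Forest Prediction of Amyloid Proteins from Sequence Features
Version: 1.0.0
Authors@R: person("Amyforest", "Maintainers", email = "maintainers@amyforest.dev",
    role = c("aut", "cre"))
Description: Sequence-only feature encoders and a random-forest classification
    pipeline for identifying amyloid-forming proteins. Implements the 188-dimension
    composition + physicochemical composition/transition/distribution (CTD)
    descriptor, the sequence-derivable members of the Pse-in-One encoder family
    (k-mer, distance-based residue, distance pair, auto/cross covariance,
    physicochemical distance transformation, parallel- and series-correlation
    pseudo amino-acid composition), n-gram and 400-dimension skip-gram baselines,
    a CART random forest with majority voting, stratified k-fold cross-validation,
    external 80/20 validation, balanced undersampling, the full
    SE/SP/ACC/MCC/Precision/Recall/F-measure metric suite with ROC/AUC, and a
    seeded synthetic two-class sequence generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
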