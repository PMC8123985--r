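Package: strucclass
Title: Protein Structural Class Prediction with Random-Forest Feature
    Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the SCOP-style structural class of a protein
    (all-alpha, all-beta, alpha/beta, alpha+beta) from its amino-acid
    sequence and a predicted three-state secondary-structure string.
    Implements four feature families (k-word content features, interval
    distance position features, reduced-alphabet hydrophobicity features,
    and secondary-structure segment descriptors), a random-forest
    relative-importance (RI) feature-selection algorithm built on
    entropy/information-gain decision trees, and a one-vs-one RBF-SVM
    classifier with dyadic grid search and jackknife (leave-one-out)
    evaluation.  A synthetic benchmark generator emits labelled
    (sequence, secondary structure, class) triples with class-dependent
    segment architecture so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
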