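Package: acsclass
Title: Pattern-Recognition Classification of Acute Coronary Syndrome Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for multi-class classification of acute
    coronary syndrome (STEMI, NSTEMI, unstable angina, other) from coded
    clinical features. Provides a mixed-scale clinical feature schema with
    min-max normalization, a seeded synthetic-data generator with planted
    informative features, eight classical supervised learners (GLM one-vs-rest,
    k-nearest neighbours, Naive Bayes, ID3 decision trees, bagged ID3, a
    single-hidden-layer perceptron, radial basis function networks, and a
    Sugeno-type neuro-fuzzy regressor) under a common fit/predict contract, a
    k-NN-wrapped sequential backward-elimination feature selector, repeated
    random sub-sampling validation with two- and three-way splits, and
    confusion-matrix conditional-probability metrics (accuracy and correctness
    probability matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
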