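Package: lssvmbdt
Title: Fetal-State Classification from Cardiotocograms with Least-Squares
    SVMs, Particle Swarm Optimization and a Binary Decision Tree
Version: 0.1.0
Authors@R:
    person("Deniz", "Arslan", email = "deniz.arslan@example.org",
           role = c("aut", "cre"))
Description: Three-class fetal-state classification (normal, suspect,
    pathologic) from 21-feature cardiotocogram (CTG) tables. A binary
    least-squares support vector machine (LS-SVM) with a Gaussian RBF
    kernel is trained by solving its linear Karush-Kuhn-Tucker system;
    the penalty factor and kernel width are tuned by particle swarm
    optimization; the binary classifier is extended to R classes with a
    binary decision tree of R-1 node classifiers. Includes stratified
    k-fold cross-validation, confusion and confusion-ratio matrices,
    one-vs-rest sensitivity/specificity, cobweb misclassification plots
    with the chance polygon, a CSV reader for the UCI CTG feature schema,
    a synthetic three-class Gaussian generator with CTG-like class
    imbalance, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Config/testthat/edition: 3
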