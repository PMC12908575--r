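Package: bcti
Title: Bayesian Critical Transition Inference for Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint inference of gene regulatory networks and detection of
    critical transitions from stage-wise gene expression data. Builds an
    undirected correlation basis network from Gaussian mutual information,
    searches for the optimal directed acyclic graph by restart hill-climbing
    under a structural-equation-model fit with a minimum-description-length
    penalty, and tracks the optimal network score across ordered stages to
    flag the pre-transition (critical) state. Includes a Michaelis-Menten
    stochastic-differential-equation bifurcation simulator, a planted-
    transition synthetic data generator, and confusion-matrix evaluation of
    directed networks against gold standards.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
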