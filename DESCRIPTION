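Package: stgcn
Title: Spatial-Temporal Graph Convolutional Networks for Tennis Stroke
    Recognition from Motion-Capture Skeletons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tennis motion sequences (forehand, backhand, no-shot)
    from optical motion-capture data using a three-layer spatial-temporal
    graph convolutional network over a reduced 19-node human-plus-racket
    skeleton. Supports trapezoidal fuzzification of coordinate channels,
    an "active features" knowledge base of joint kinematics and posture
    triangles fused with the network output, a C3D motion-capture reader
    and writer with a plain-text CSV fallback, a kinematic synthetic-data
    generator emulating three-phase stroke sequences, and a train-fraction
    sweep protocol with paired fuzzy versus raw comparisons. The network,
    including backpropagation and stochastic gradient descent training, is
    implemented in base R on top of BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
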