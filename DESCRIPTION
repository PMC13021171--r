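Package: neotongue
Title: Finite Element Simulation of Free-Flap Tongue Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated virtual testbed for free-flap tongue reconstruction
    surgery. Assembles a multi-component (skin + adipose) flap model inside a
    resected tongue, insets it with cluster-spring sutures and shortening
    tension elements, equilibrates the viscoelastic neotongue, and simulates
    one year of post-operative flap atrophy as isotropic negative kinematic
    growth. Ships Yeoh and Ogden hyperelastic laws with Prony-series
    quasi-linear viscoelasticity, an evolutionary calibrator for two-term
    Ogden fits to uniaxial stress-stretch data, outcome metrics
    (percentile Hausdorff surface deviation, von Mises equivalent strain),
    and a full-factorial study driver with hierarchical OLS analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
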