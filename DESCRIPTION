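Package: softinverse
Title: Inverse Identification of Hidden Material Abnormalities in Soft Bodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Non-destructive recovery of hidden material parameters and the
    shape and position of stiff internal abnormalities in soft hyperelastic
    bodies, by matching large surface deformations between an observed
    "physical" object and a finite-element virtual twin. Ships a nonlinear
    finite-element forward solver (nearly incompressible Neo-Hookean and
    Saint Venant-Kirchhoff materials, hexahedral solids and membrane
    triangles, quasi-static and transient modes), parametric abnormality
    generators (brick and revolved-curve shapes), a gradient-free batch
    Bayesian optimizer with a random-forest surrogate and a
    moment-generating-function acquisition criterion, shape-recovery
    metrics (structural similarity on spherical-map and PCA projections),
    and a registry of benchmark cases (bending beam, inflating balloon,
    simplified tri-leaflet aortic valve).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    lhs,
    ranger,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
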