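Package: generictda
Title: Thermodynamically Consistent Learning of Constitutive Models with
    Topological Data Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven identification of constitutive laws from noisy
    mechanical test data under the GENERIC (metriplectic) formalism.
    Fits per-window Poisson and friction operators together with discrete
    energy and entropy gradients by constrained regression, so that the
    learned dynamical model conserves energy and produces entropy by
    construction.  Experimental dispersion is handled by Vietoris-Rips
    persistent homology over experiment descriptors, neighbour detection on
    the constitutive manifold, and simple, ordinary and local (tangent-chart)
    Kriging interpolation of the model terms.  Includes a visco-hyperelastic
    (Mooney-Rivlin plus Prony series) plane-stress biaxial test simulator and
    a synthetic arterial stress-stretch curve family generator used as
    benchmark inputs, plus end-to-end drivers for both studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
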