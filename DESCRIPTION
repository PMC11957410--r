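Package: glwave
Title: Generalized Leveled-Wave Modelling of Distorted Lamellar Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates distorted lamellar and sponge-like membrane phases as
    clipped superpositions of anisotropic random waves, computes their
    small-angle scattering spectra by fast Fourier transform with radial
    averaging, trains a two-stage Kolmogorov-Arnold spline network that maps
    structural parameters (radial dispersion, orientational order, membrane
    volume fraction) to scattering intensity, inverts measured
    one-dimensional scattering curves to those parameters by least squares,
    and locates, classifies and tracks topological defect lines as phase
    singularities of the complex wave field via a winding-number scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    splines,
    jsonlite,
    lhs
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
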