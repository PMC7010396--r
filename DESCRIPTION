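Package: sphtrack
Title: Sub-Riemannian Geodesic Tracking of Vessels in Spherical Retinal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks curvilinear structures (retinal blood vessels) in spherical
    images by data-driven sub-Riemannian geodesics in the rotation group SO(3).
    Provides the schematic-eye projection between flat fundus images and
    spherical object coordinates, exact sub-Riemannian geodesics with cusp
    analysis, an anisotropic eikonal solver on the (x, y, theta) chart driven
    by a multiscale Hessian vesselness cost, and geodesic backtracking with
    curvature read-out on the sphere.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    pracma,
    stats,
    utils,
    tools,
    tibble,
    generics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    png,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
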