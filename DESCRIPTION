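Package: entropack
Title: Maximum-Entropy Statistics of Cellular Packing in Multicellular Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how cells partition space in simple
    multicellular groups. Simulates diverse growth morphologies (tree-like
    budding, aggregation, palintomy within a membrane, cells on a spherical
    surface, patterned growth with placement noise, localized apoptosis),
    computes cell neighborhood sizes by clipped 3D Voronoi tessellation and
    by surface Voronoi tessellation with solid angles, and tests the
    maximum-entropy k-gamma prediction for the neighborhood-size
    distribution via moment matching and P-P residual diagnostics. Also
    includes network-distance spatial correlation and hexatic order
    diagnostics, a weakest-link model linking cell packing to group-size
    distributions, and Legendre-mode swimming-speed calculations for
    spherical microswimmers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
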