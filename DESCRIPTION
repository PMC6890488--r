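Package: curveflow
Title: Adaptive Moving-Mesh Evolution of Closed Plane Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Evolves closed polygonal plane curves under forced curve
    shortening flow, where the normal velocity is a curvature term plus an
    external forcing. Mesh quality along the evolving curve is maintained by
    a tangential node velocity derived from a moving-mesh PDE that relaxes
    the mesh towards equidistribution of a curvature-based monitor function.
    Provides first-order (backward Euler) and second-order (Crank-Nicolson /
    backward Euler hybrid) implicit time integrators solved by Picard
    iteration on a cyclic block-tridiagonal system, de Boor equidistribution
    for initial mesh generation, named benchmark curves, enclosed-area error
    norms and convergence-order diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    readr,
    rlang,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
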