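Package: valvemorph
Title: Phylogenetic Geometric Morphometrics of Paired Valve Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the macroevolution of paired shell valves
    with three-dimensional landmark data: generalised Procrustes
    superimposition with sliding semilandmarks, quantification of matching
    (directional) asymmetry between left and right valves, evolutionary
    integration via phylogenetic two-block partial least squares,
    phylogenetic generalised least squares for multivariate traits, and
    multivariate Brownian-motion rate estimation with group and trait
    comparisons, permutation and simulation based significance tests, and
    bootstrap confidence intervals. A synthetic-shell generator emulates a
    multi-species museum sample of scallop valves for simulation studies
    and end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
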