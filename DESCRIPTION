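Package: feasdom
Title: Size and Shape of the Feasibility Domain of Lotka-Volterra Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric analysis of feasibility (coexistence) in generalized
    Lotka-Volterra communities. Computes the normalized volume of the cone of
    intrinsic growth rates compatible with a feasible, globally stable
    equilibrium, via exact orthant-probability reduction with log-space
    randomized quasi-Monte Carlo, direct sphere sampling, and closed-form
    approximations for large random interaction matrices. Characterizes the
    shape of the feasibility cone through the side lengths of its spherical
    simplex and their moments. Includes random-matrix ensembles with
    prescribed coarse-grained moments, parameterizations of mutualistic
    (bipartite) and food-web interaction networks with calibrated interaction
    strengths, cascade and randomization null models, and readers for
    incidence-matrix and edge-list network files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    stats,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
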