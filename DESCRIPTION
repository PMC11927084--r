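Package: affpol
Title: Affective Polarization Dynamics of Binary Choices on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how binary choices (masking, vaccination,
    consumer choices) spread through a society split into two antagonistic
    groups. Individuals conform to same-group neighbours (in-group love,
    alpha) and oppose other-group neighbours (out-group hate, beta), with an
    inertia threshold delta. The package provides the stochastic
    agent-based dynamics on arbitrary labelled graphs, the piecewise-smooth
    mean-field limit ODE with an exact event-driven integrator, analytic
    classification of the consensus / partisan / nonpartisan regimes,
    consensus-reachability tests from group-dependent initial states,
    switching-manifold (tipping point) computation, stochastic block model
    generators parameterized by homophily, assortativity-targeted group
    assignment for real networks, and reproducible experiment recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
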