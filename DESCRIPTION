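Package: lvfeas
Title: Feasibility of Equilibria in Large Lotka-Volterra Ecological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether large generalized Lotka-Volterra
    communities admit feasible (all-positive) equilibria. Provides random
    and ecologically structured food-web generators (Erdos-Renyi, cascade,
    niche, nested-hierarchy), signed Gaussian and folded-Gaussian
    interaction matrices scaled by linkage density, linear-solve equilibria
    with conditioning diagnostics, spectral stability via the community
    matrix, May's stability criterion, closed-form feasibility asymptotics
    for the moderate-interaction regime, and a Monte-Carlo pipeline that
    estimates the feasibility probability across interaction-strength
    regimes, network architectures and species richness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
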