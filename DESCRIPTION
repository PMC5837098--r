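Package: sowsim
Title: Monte Carlo Simulation of Single-Seed Precision Sowing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Stochastic field-scale simulation of single-seed precision
    sowing in maize. Generates Bernoulli seedling-emergence grids on
    rectangular planting layouts, models yield as a vertex-form parabola
    in planting density with a tangent-angle density-sensitivity
    parameterization, compensates missing plants through field-clipped
    Voronoi nutrition areas, computes connected-component statistics of
    seedling-missing spots with quadratic and exponential distribution
    laws, and compares sowing at the optimum density against sowing
    inflated by the reciprocal of the emergence rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
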