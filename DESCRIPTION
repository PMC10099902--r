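Package: eleaf
Title: Three-Dimensional Reaction-Diffusion Modelling of Rice Leaf
    Photosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation of C3 photosynthesis in a rice leaf
    resolved at the level of individual mesophyll cells.  A parametric
    generator builds periodic voxelised leaf-anatomy unit cells (lobed
    mesophyll cells, bundle sheath, bulliform cells, epidermis) that match
    user-set porosity and exposed mesophyll surface area.  A Monte-Carlo
    ray tracer propagates light through the labelled volume, a
    finite-volume solver computes the coupled steady-state diffusion of
    gaseous CO2, dissolved CO2 and bicarbonate, and
    Farquhar-von-Caemmerer-Berry metabolism evaluated per chloroplast
    closes the system, yielding leaf-level assimilation and PSII quantum
    yield.  Includes genetic-algorithm estimation of photosynthetic
    parameters from combined gas-exchange/fluorescence curves, and
    in-silico experiments: light x CO2 response surfaces, factor-group
    substitution between growth conditions, and anatomy sweeps with
    replicate ensembles and ANOVA significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
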