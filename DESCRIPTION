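Package: crmsize
Title: Transient Cell-Size Dynamics Under a Continuous-Rate Division Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transient dynamics of cell size for exponentially growing cells
    that divide with a size-proportional splitting rate h = k*s (generalized
    h = k*s^lambda), the continuous-rate counterpart of the adder division
    strategy. Solves the division-counting master equation by a recursive
    quadrature of its closed-form solution and by finite state projection
    (FSP) with explicit truncation-error (leak) accounting, simulates exact
    single-cell lineages by inverse-transform sampling of the time-varying
    division hazard, and assembles the time-dependent cell-size distribution
    of a fixed (mother-machine) population as a weighted Dirac mixture with
    its moments, envelopes over initial sizes, and initial-size-distribution
    mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Matrix,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
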