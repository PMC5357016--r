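Package: socioscape
Title: Landscape Connectivity and Proximity-Based Social Networks from GPS
    Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking landscape composition and connectivity to the
    social network structure of GPS-collared animals. Builds proximity-based
    association networks from collar fix tables (simultaneity matching,
    association rates, data-sufficiency diagnostics), estimates kernel
    utilization distributions with reference-bandwidth smoothing and the PHR
    and VI overlap indices, maps omnidirectional circuit-theory current
    density over categorical land cover, computes local (average weighted
    degree) and global (subset-normalised weighted closeness) social network
    metrics, and fits the accompanying statistical layer: Box-Cox
    transformation, AICc model selection and averaging, permutation F-tests,
    and univariate cross-network regressions. A synthetic-data generator
    simulates group-structured deer-like movement over patchy landscapes with
    known ground-truth association rates so that every pipeline stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    MASS,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
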