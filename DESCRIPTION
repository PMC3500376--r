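Package: corridorscope
Title: Habitat Suitability and Connectivity Models for Migration Corridor Delineation
Version: 0.1.0
Authors@R:
    person("Corridorscope", "Developers", email = "corridorscope@example.org",
           role = c("aut", "cre"))
Description: Tools for delineating and evaluating seasonal wildlife migration
    corridors on raster landscapes. Implements a presence-only maximum-entropy
    habitat suitability model and an expert-based Analytic Hierarchy Process
    model, converts either suitability surface into a movement resistance
    surface, and compares two connectivity engines on top of them: least-cost
    corridor mapping (multi-source cost-distance accumulation) and
    circuit-theory connectivity (graph-Laplacian current flow between focal
    habitat patches). Corridors are sliced at percentile thresholds of the
    corridor-cost or current surface and scored against GPS telemetry by the
    fraction of migration fixes captured per unit study area, including a
    tiered priority-area overlay. A synthetic prairie landscape and migratory
    telemetry generator makes the full factorial pipeline testable end to end
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
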