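Package: maupsim
Title: Simulated Zonal Aggregation Sandbox for the Modifiable Areal Unit
    Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A seeded, density-preserving spatial aggregation simulator for
    studying the modifiable areal unit problem (MAUP) in population
    aggregation and dasymetric disaggregation. Coarsens a polygonal
    census-like tessellation across a schedule of resolution levels by
    quasi-randomly selecting small units and dissolving each into the
    contiguous neighbour with the most similar population density, logging
    every merge so simulations can be replayed. Includes a synthetic
    census-landscape generator (Voronoi tessellations with heavy-tailed unit
    areas and an area-density anticorrelation), evaluation statistics
    (average spatial resolution, log-scale distribution summaries,
    unit-merge frequency, the normalised difference population index,
    bootstrap intervals), and a mass-preserving dasymetric disaggregation
    harness with pluggable pixel weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
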