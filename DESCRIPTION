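Package: sapm
Title: Spatial Access Priority Mapping for Fishing Fleets
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative participatory-GIS mapping of fishing fleets' spatial
    access priorities. Converts interview-drawn priority polygons into
    fleet-wide, per-fishery and relative spatial-access-priority (SAP) rasters
    on an equal-area grid, with pro-rata crew accounting, stratified
    sample-to-fleet up-scaling weights (with donor fallback for unsampled
    port-gear-length strata), representativeness and response-consistency
    statistics, closure-impact analysis, and Marxan cost-layer export. Includes
    a synthetic fleet and survey generator so the full pipeline is testable
    without confidential interview data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    geosphere,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
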