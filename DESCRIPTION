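Package: crowdvol
Title: Citizen-Science Subject Generation and Consensus Aggregation for
    Volumetric Bioimages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for running crowdsourced annotation campaigns on 3D
    grayscale image volumes. Cuts volumes into padded, overlapping tiles and
    multi-slice flipbook subjects with provenance manifests; parses
    classification exports (CSV with embedded JSON annotations) into typed
    records; aggregates volunteer responses into consensus results: majority
    voting with early-retirement analysis for question tasks, density-based
    spatial clustering (DBSCAN) with outlier removal and location averaging
    for point and ellipse marks, and contour regression by interior averages
    (CRIA) for freehand outlines; and reassembles per-subject consensus back
    into volume coordinates. Includes a synthetic phantom-and-volunteer
    simulator so every stage can be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    utils,
    stats,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
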