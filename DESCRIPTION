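Package: retscn
Title: Structural Covariance Networks of Retinal Layer Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds group-level structural covariance networks from ETDRS-grid
    retinal layer thickness measurements (7 layers by 9 macular sectors),
    detects community structure with a resolution-parameterised Louvain
    modularity optimiser and 50-run consensus, compares modularity between a
    diabetic-without-retinopathy-like group and healthy controls, and fits
    per-sector age trajectories compared across groups with Fisher's r-to-z
    transform under false-discovery-rate control. Includes a synthetic cohort
    generator with planted block-covariance structure so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
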