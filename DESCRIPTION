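Package: pcawarp
Title: Statistical Shape-Model Individualization of M/EEG Head Models from Scalp Proxies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a low-dimensional principal-component shape model over
    populations of nested four-shell head surface meshes (scalp, skull, CSF,
    cortex) sharing a common triangulation, and estimates an individual's full
    head geometry from a scalp proxy (photogrammetry point cloud or digitized
    electrode positions) by optimizing shape-model weights under vertex-distance
    or raytraced shape-difference metrics with an inter-shell proximity penalty.
    Includes a thin-plate-spline template-warp baseline, a synthetic head
    population generator, mesh and point-cloud I/O, and an evaluation harness
    with shape-error reports, residual-variance dipole fitting over an analytic
    spherical forward model, and paired model-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
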