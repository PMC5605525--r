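Package: panclonal
Title: Stochastic Clonal Models of Pancreas Organogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for clonal lineage tracing of the
    embryonic mouse pancreas. Provides a stochastic branching-process
    simulator of clonal expansion from single E9.5 progenitors under two
    competing endocrine/acinar fate-bias models (constant bias, and a
    time-varying bias with a cosine minimum near E12), gamma-distributed
    cell-cycle sampling, kernel-density likelihoods with an AIC-based model
    comparison over a (c, q) parameter scan, clone potency classification and
    labelling statistics, 3D Delaunay neighbour graphs with distance pruning
    for bud-scale expression analysis, projection of labelled cells onto the
    dorsal pancreas length axis for label-retention analysis, and synthetic
    data generators that emulate the imaging-derived inputs so every analysis
    runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
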