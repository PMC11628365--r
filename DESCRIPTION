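Package: quadfold
Title: Path Collective Variables, Metadynamics Reweighting and
    Minimum-Energy-Path Analysis for G-Quadruplex Folding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for the computational protocol used in
    enhanced-sampling studies of DNA G-quadruplex folding: structural metrics
    (Kabsch RMSD, the base-arrangement-sensitive epsilon-RMSD, and a combined
    RMSD/epsilon-RMSD distance), Branduardi-style path collective variables
    over milestone sets, nudged-elastic-band path optimization with the
    improved (Henkelman-Jonsson) tangent, well-tempered metadynamics with
    orthogonal-distance restraint walls and REST2 ladder utilities, binless
    WHAM and property-map free-energy-surface construction with block
    standard errors and restraint-bias corrections, and Dijkstra
    minimum-energy-path extraction over a folding-state cube. Exercised on
    toy landscapes and synthetic G-tract structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
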