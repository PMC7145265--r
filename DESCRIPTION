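Package: msmgating
Title: Markov State Model Analysis of Ion-Channel Conformational Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing conformational gating of
    ion channels from dihedral-angle time series: time-lagged independent
    component analysis (tICA) with kinetic mapping, mini-batch k-means
    microstate clustering, reversible Markov state model (MSM) estimation with
    bootstrap uncertainty, PCCA+ kinetic coarse-graining, continuous-time
    rate-matrix estimation among macrostates, free-energy landscapes along slow
    coordinates, pore-radius profiling of conduction pathways, and
    binding-site occupancy statistics. Includes a synthetic-data module that
    generates trajectories from a calibrated reference kinetic model of a
    CLC-2-like selectivity filter (closed, inner-open, open, and
    protonation-only occluded states), so every stage is testable against known
    ground truth without molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    igraph,
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
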