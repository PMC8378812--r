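Package: lipidsites
Title: Lipid Binding-Site Detection from Coarse-Grained Membrane Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of lipid interactions with membrane proteins from
    coarse-grained trajectories: leaflet-resolved lipid binding propensity,
    z-profiles of lipid-contacting residues, lipid-bead interaction
    profiles, dual-cutoff (hysteretic) binding kinetics, graph-based
    identification of discrete lipid binding sites with occupancy and
    residence-time metrics, annotation of sites by adjacent basic residues,
    and a rule engine scoring candidate cardiolipin sites on
    membrane-oriented structures. Includes a synthetic trajectory generator
    that plants binding sites with known two-state kinetics so the whole
    pipeline is testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
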