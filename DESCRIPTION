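Package: hydropore
Title: Hydrophobic Gating Analysis of Channel Pore Hydration in MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis of hydrophobic gating in ion channel pores.
    Reads structures (PDB, GRO) and trajectories (multi-model PDB, DCD),
    defines a pore-centered coordinate system anchored at a selectivity-filter
    ion-binding site, and computes anchor-referenced box occupancy time series
    for water oxygens and lipid carbons, percent-occupancy summaries, wet/dry
    state segmentation with transition-rate estimates, joint water-lipid
    occupancy heat maps, bulk-normalized three-dimensional water density grids
    (OpenDX output), and pore-radius-versus-z profiles of the conduction
    pathway. Includes a synthetic trajectory generator with planted,
    closed-form ground truth (telegraph-process hydration, state-coupled lipid
    tail insertion) for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
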