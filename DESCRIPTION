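Package: watsite
Title: Hydration-Site Prediction and Consensus Water Analysis from
    Molecular Dynamics Water Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Locates high-density hydration sites around a fixed solute
    from molecular dynamics water-oxygen trajectories and scores each
    site by the excess chemical potential of water (the "work to
    transfer" from bulk), estimated from the local-to-bulk density ratio
    on a fine voxel grid with Boltzmann averaging over the densest
    voxels.  Also clusters experimentally modelled waters across
    superposed structures into high- and lower-consensus groups, and
    evaluates predicted against experimental water positions by
    one-to-one distance matching with precision and recall.  A synthetic
    trajectory and pseudo-structure generator with analytic expectations
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
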