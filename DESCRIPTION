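Package: otodrill
Title: Voxel-Based Haptic Temporal-Bone Drilling Simulation Engine
Version: 0.1.0
Authors@R: person("Otodrill", "Developers", role = c("aut", "cre"),
    email = "otodrill@example.org")
Description: A headless, fully testable engine for voxel-based haptic
    simulation of temporal-bone (mastoid) drilling.  Builds labeled voxel
    models from segmented volumetric imaging (NRRD, NIfTI-1, raw+JSON) and
    watertight structure meshes (PLY, STL, OBJ); extracts polygonal surfaces
    with chunked, incrementally updatable Marching Cubes followed by
    Laplacian HC smoothing; carves drillable material with a spherical burr
    under per-tissue ease, resistance and undrillable protection with
    stroke-level undo; renders contact forces with a position-locking
    (proxy) algorithm alongside a classical virtual-spring baseline; and
    records, replays and guides drilling sessions for passive and active
    hand-motion training.  A synthetic temporal-bone phantom generator with
    analytic ground truth supports end-to-end verification.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
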