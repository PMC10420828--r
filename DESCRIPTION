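Package: mechprof
Title: Active-Site Trajectory Analysis and Cluster-Model Reaction Energy Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of enzyme active-site molecular dynamics
    trajectories and assembly of quantum-cluster reaction energy profiles.
    Provides hydrogen-bond and water-bridge detection with occupancy
    statistics, Kabsch-superposed RMSD series, reactive-distance time
    series, selection and classification of catalytically competent
    frames, construction and validation of truncated quantum-cluster
    active-site models with frozen-boundary bookkeeping, composite
    reaction-barrier assembly from electronic, solvation and zero-point
    energy components, and Eyring transition-state-theory interconversion
    of rate constants and free-energy barriers.  A synthetic-trajectory
    generator with exact ground truth makes every stage testable without
    molecular dynamics or quantum chemistry runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
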