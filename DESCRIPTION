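Package: leadfunnel
Title: Consensus Docking Rank Aggregation and Stability Triage for
    Lead Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of the computational funnel used
    to prioritize natural-product inhibitor candidates against a protein
    target: multi-program docking-score consensus by radar-polygon-area rank
    aggregation, conceptual-DFT global reactivity descriptors from frontier
    orbital energies, from-scratch molecular-dynamics trajectory analytics
    (Kabsch-superposed RMSD, per-residue RMSF, radius of gyration,
    Shrake-Rupley solvent-accessible surface area, geometric hydrogen-bond
    counting, Cartesian PCA and Boltzmann-inversion free-energy landscapes),
    MM-PBSA component bookkeeping with quadrature error propagation, and a
    weighted multi-criteria stability score.  Seeded synthetic-data
    generators stand in for the docking, DFT and simulation engines so
    every stage is testable without external software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d,
    optparse
Config/testthat/edition: 3
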