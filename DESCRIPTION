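Package: nanobrush
Title: Structural, Energetic, Electrokinetic and Dynamic Analysis of
    Polymer-Grafted Nanoparticle Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular simulation trajectories of
    PEG-coated spherical nanoparticles in electrolyte solution. Reads
    standard coordinate formats (extended XYZ, GRO, PDB) with a JSON
    topology sidecar; computes spherically averaged number-density and
    radial-distribution profiles about the particle center, per-chain
    polymer metrics (radius of gyration, end-to-end distance, layer
    thickness) and volume-fraction profiles with a Daoud-Cotton brush-
    scaling fit; counts geometric hydrogen bonds and group-pair
    nonbonded (Coulomb + Lennard-Jones) energies; derives the charge
    density, Gauss-law electric field, electrostatic potential and zeta
    potential at the shear plane; estimates self-diffusion coefficients
    from mean-square displacements and classifies two-particle
    aggregation. Seeded synthetic-configuration generators with
    closed-form ground truth make every stage testable without
    production trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
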