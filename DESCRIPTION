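Package: gactdyn
Title: GPCR Activation-Dynamics Analysis of Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis of class A G-protein-coupled receptor (GPCR)
    activation dynamics from molecular dynamics coordinate ensembles.
    Monitors the R3.50-E6.30 ionic-lock microswitch, computes proline-kink
    geometry (bend, wobble and face-shift angles), backbone and side-chain
    dihedral statistics with circular averaging and half-trajectory
    transition detection, differential salt-bridge, hydrogen-bond and
    hydrophobic contact-occupancy networks between ensembles, combined
    principal component analysis of concatenated trajectories, dynamic
    cross-correlation matrices and helix-end membrane-plane projections.
    Includes a synthetic-trajectory generator with known ground truth
    (kink angles, lock-open fraction, contact occupancies, motion
    correlations) so every analysis stage is testable without running MD,
    plus Ballesteros-Weinstein generic-number mapping and a multi-model
    PDB reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
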