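Package: eckrot
Title: Eckart-Frame Rotational Dynamics of Bead-Model Proteins Under Shear
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Separates rotation from vibration in coarse-grained bead
    trajectories using the Eckart corotating frame. Computes the
    laboratory-frame (apparent) and Eckart angular velocities, the
    five-term kinetic-energy decomposition with the Coriolis coupling,
    conformational observables (gyration tensor, radius of gyration,
    RMSD, RMSF), breakable elastic-network bookkeeping, and the
    open-boundary momentum-flux and DPD weight-function formulas used to
    impose shear flow. Ships a synthetic-trajectory generator with
    analytically known translational, rotational, and vibrational
    content so every analysis stage can be validated against ground
    truth, plus GRO / extended-XYZ / PDB readers and writers and a small
    command-line driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
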