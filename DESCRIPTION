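Package: virialscan
Title: Second Osmotic Virial Coefficients of Rigid Biomolecules from
    FFT-Accelerated Energy Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes second osmotic virial coefficients (A2) and cross
    second virial coefficients (A23) of rigid atomistic structures from a
    three-term pair energy model (hard-core steric clash, 12-6
    Lennard-Jones attraction, Debye-Hueckel screened electrostatics) by
    FFT-accelerated integration of the Mayer f-function over translations
    and sampled orientations. Histidine protonation is handled by
    enumerating all protonation microstates with Henderson-Hasselbalch
    weights and Boltzmann-averaging the resulting virial coefficients.
    Includes mining and single-linkage clustering of lowest-energy binary
    poses with per-residue energy decomposition, Hill-equation fitting of
    NMR pH titrations, turbidity-onset threshold extraction for
    liquid-liquid phase separation assays, and principal-component
    multilinear regression of virial features against phase-separation
    threshold concentrations. Synthetic generators for rigid toy bodies,
    titration curves, turbidity series and feature tables support fully
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
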