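Package: probephase
Title: Snapshot-Based Photophysics of Membrane-Embedded Fluorescent Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for per-frame excited-state records of a
    rod-like fluorescent membrane probe (diphenylhexatriene, DPH) embedded
    in lipid bilayers of different phase (liquid-disordered DOPC, solid-gel
    DPPC, liquid-ordered sphingomyelin/cholesterol).  From snapshot
    ensembles of excitation energies, transition dipole moments, two-photon
    strengths and first-hyperpolarizability tensors it computes
    ensemble-broadened one-photon absorption spectra with photoselection
    analysis, two-photon absorption cross sections in Goeppert-Mayer units,
    hyper-Rayleigh scattering responses by exact orientational averaging,
    radiative lifetimes with refractive-index correction, fluorescence
    anisotropy decays, and backbone dihedral/conformer statistics.  A
    seeded synthetic frame generator emulates the phase-specific
    statistical structure of the three membrane environments so the whole
    pipeline is testable without quantum-chemistry or molecular-dynamics
    engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    pracma,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
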