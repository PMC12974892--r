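Package: emler
Title: Electrostatic Machine-Learning Embedding for ML/MM Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electrostatically embedded machine-learning / molecular
    mechanics (ML/MM) simulations at desk scale. Implements the EMLE energy
    decomposition into gas-phase, static, induced and MM components; static
    electrostatics from conformation-dependent atomic charges and spherical
    Slater valence densities with charge penetration; Thole induced-dipole
    polarization with fixed and environment-flexible polarizability-to-volume
    ratios; sparse Gaussian-process models of per-atom properties; embedding
    ablations (mechanical and fixed-charge MM embedding); Langevin dynamics,
    umbrella sampling and WHAM free-energy profiles with replica and
    fragment-based uncertainty estimates; per-component error analysis and
    radial distribution functions; and a synthetic ground-truth generator that
    emulates gas-phase quantum-chemical reference data for training and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
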