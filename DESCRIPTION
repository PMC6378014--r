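Package: adiposim
Title: Agent-Based Simulation of Adipose Tissue Growth and Metabolic Inflammation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulator of visceral adipose tissue under
    sustained caloric surplus. Individual adipocytes swell probabilistically
    toward a gender-specific critical size, supercritical cells trigger
    recruitment of new adipocytes (hyperplasia) and secrete proinflammatory
    cytokines, and a macrophage population drifts toward the proinflammatory M1
    phenotype. Body weight is mapped from simulated tissue volume through
    anthropometric fat-mass relations. Includes protocol fixtures for two
    classical human overfeeding studies, replicate management with full
    reproducibility manifests, energy sweeps, inflammation-onset detection and
    Kaplan-Meier onset curves, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
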