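Package: egfrsim
Title: Multiscale Brownian-Dynamics Simulation of EGFR/ERK Signalling and
    Tumour Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 3D multiscale agent-based simulator of early tumour growth
    driven by EGFR/ERK signalling. Extracellular epidermal growth factors
    (EGF) diffuse by Brownian motion in a spherical domain and bind membrane
    EGFR clusters; inside every cell a particle-based Brownian-Dynamics model
    propagates the Ras -> Raf -> ERK -> transcription-factor cascade with
    reaction-radius overlap kinetics; cells are soft spheres with
    incompressible nuclei that move under pairwise repulsion, pass or fail a
    transcription-factor checkpoint at the end of G1, grow, divide, or die by
    apoptosis. The three subsystems are coupled by operator splitting.
    Scenario runners reproduce single-cell mutation experiments (K-Ras,
    B-Raf), receptor-placement experiments, and multicellular tumour-growth
    experiments with EGFR overexpression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
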