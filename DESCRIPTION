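Package: gatekin
Title: Active-Site Gate Dynamics and Ubiquitination Kinetics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for studies of active-site gate
    dynamics in ubiquitin-conjugating (E2) enzymes. Fits enzyme-kinetics
    models (exponential conjugation/hydrolysis/aminolysis rates, the
    quadratic neutral-lysine aminolysis rate law, and a six-species
    coupled-ODE model of K48-linked di-ubiquitin chain synthesis), analyses
    NMR titrations (chemical shift perturbations, 1:1 binding isotherms
    with ligand depletion, Bloch-McConnell two-site exchange lineshapes),
    back-calculates 15N R1/R2/NOE relaxation rates from correlation-function
    models, and characterises conformational gating from molecular-dynamics
    distance trajectories (two-state digitisation, transition-rate barrier
    estimation via the Eyring equation, and steered-work free-energy
    profiles via the second-order Jarzynski cumulant expansion). Includes
    seeded generators for every input class so all analyses are testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
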