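Package: pressim
Title: Agent-Based Simulation of Pressure Ulcer Formation by Ischemia/Reperfusion and Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A stochastic two-dimensional tissue simulator of pressure ulcer
    formation in which blood-vessel constriction under cyclic pressure causes
    ischemia, xanthine-oxidase accumulation and reperfusion injury by reactive
    oxygen species, and in which stressed tissue recruits an inflammatory
    cascade (DAMPs, neutrophils, TNF-alpha, M1/M2 macrophages, IL-1beta,
    TGF-beta1) that can become self-sustaining. Includes the analysis suite
    used to interrogate the model: Gaussian-mixture discovery of bimodal damage
    outcomes, 1-nearest-neighbour trajectory classification, checkpoint-restart
    commitment-time experiments, parameter sensitivity sweeps, and in-silico
    treatment trials of corticosteroids and anti-DAMP antibodies, plus snapshot
    rendering and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
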