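Package: nvcsim
Title: Forward Simulation of Astrocyte-Mediated Neurovascular Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A forward simulator of the neuron-astrocyte-vascular pathway that
    transforms an external stimulus into a BOLD signal through four coupled
    stages: an adaptive-exponential (AdEx) mean-field description of a
    recurrent cortical population, glutamate-driven astrocytic IP3/calcium
    dynamics (a Li-Rinzel model extended with agonist-dependent IP3
    metabolism), an arachidonic-acid/prostaglandin-E2 vasodilation cascade
    acting through smooth-muscle cAMP, and the Balloon model of venous volume
    and deoxyhemoglobin. Includes stimulus-protocol constructors
    (event-related, block, sinusoidal), a deterministic fixed-step integrator,
    and an analysis toolkit: calcium-spike detection and coding curves,
    hemodynamic-response-function (HRF) feature extraction, canonical
    double-gamma HRF fitting, convolution-based linear prediction, and
    post-stimulus undershoot decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
Config/testthat/edition: 3
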