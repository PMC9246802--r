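Package: cnspbpk
Title: Physiologically Based Pharmacokinetics of Drug Distribution in Brain and CSF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compartmental physiologically based pharmacokinetic (PBPK)
    simulator for unbound small-molecule drug distribution in the human
    central nervous system. Implements a nine-compartment brain and
    cerebrospinal-fluid model (microvascular blood, brain extracellular and
    intracellular fluid, lysosomes, and the ventricular-to-subarachnoid CSF
    chain) driven by an empirical unbound plasma forcing function, with
    pH-dependent transcellular transport, paracellular diffusion, asymmetry
    factors calibrated against unbound partition coefficients (Kpuu),
    phospholipid-based nonspecific tissue binding, and physiological fluid
    flows. Ships physiology translation from cognitively healthy young adults
    to elderly and mild Alzheimer's populations, a registry of five
    Alzheimer's drugs, steady-state exposure metrics compared against unbound
    IC50, one-at-a-time sensitivity analysis, and synthetic data generators.
License: MIT
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
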