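Package: hhenergetics
Title: Energy Supply and Consumption Analysis for Hodgkin-Huxley Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single Hodgkin-Huxley neuron under step-current
    stimulation and computes the metabolic energetics of its activity: ATP
    energy supply by counting the Na+ ions the Na+/K+ pump must extrude,
    electric energy consumption as the time integral of channel power
    dissipation, the resulting energy efficiency, inner-product synchrony
    between channel currents and powers, and stimulus sweeps that separate
    subthreshold activity (efficiency above 100 percent, an energy
    "overdraft") from action-potential firing (efficiency near 76 percent).
    Includes an energy-form Hebbian weight-update rule on pairs of neuron
    power traces, configuration input and output, and ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
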