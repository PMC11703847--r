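Package: fearsim
Title: Spiking-Network Simulation of Fear Conditioning, Extinction and Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biologically grounded spiking-network simulator of the rodent
    fear and stress circuit. Conductance-based integrate-and-fire populations
    of the amygdala, hippocampus, medial prefrontal cortex and nucleus
    reuniens are wired from a declarative network specification, with
    spike-timing-dependent plasticity on designated projections,
    k-winner-take-all sparse coding in the hippocampus, and stress-hormone
    (norepinephrine, corticosteroid) neuromodulation. A protocol engine runs
    contextual fear conditioning, shock-magnitude, stress-enhanced fear
    learning, shock-stress ordering and immediate-extinction-deficit
    experiments, reading out freezing behavior from central-amygdala
    activity; replicate batteries, boxplot summaries and convergence
    analysis summarize the results as tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
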