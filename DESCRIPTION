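Package: dgnet
Title: Stochastic Network Model of Dentate Gyrus Epileptogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates epileptogenesis in a dentate gyrus microcircuit of
    granule cells, mossy cells and interneurons modelled as stochastic
    binary (McCulloch-Pitts) neurons. Synaptic connectivity is rewired by
    homeostatic compensation (activity-dependent synaptic-element pools),
    Hebbian and anti-Hebbian rules; slow non-synaptic excitatory and
    inhibitory processes ignite and terminate ictal episodes; and a
    transient excitatory-GABAa protocol reproduces the status epilepticus,
    latent period and spontaneous epileptiform activity sequence. Provides
    experiment schedules, parameter sweeps with replicate seeds, event
    detection, latency and connectivity-change statistics with ANOVA and
    Dunnett comparisons, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    multcomp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
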