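Package: gliamass
Title: Neuron-Astrocyte Mass Model Simulation and Bifurcation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a bilaterally coupled
    neuron-astrocyte mass model of local field potential (LFP) dynamics.
    A three-population neural mass (pyramidal, secondary pyramidal,
    interneuron) is coupled to an astrocytic compartment tracking
    extracellular and astrocytic glutamate and GABA, whose concentrations
    feed back onto the populations' excitability thresholds. Provides
    fixed-step stochastic simulation of noise-induced spiking, closed-form
    equilibrium curves with saddle-node/SNIC and Hopf localization, the
    activation-threshold map p_SNIC(v1, v2), classification of astrocytic
    glutamate-uptake deficiency regimes, and scripted in-silico protocols
    (GABA bolus, uptake knockouts) with LFP spike and frequency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
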