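Package: dendka
Title: Dendritic A-Type Potassium Conductance and GABAergic Control of
    Calcium Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of GABAergic inhibition of
    back-propagating action potential (bAP) evoked calcium signals in the
    apical dendrite of a layer-5 pyramidal neuron. Provides a branched
    compartmental cable model with implicit (backward) Euler integration,
    Hodgkin-Huxley style sodium and potassium channels, a linearly graded
    A-type potassium conductance, a reporter calcium channel, and a
    biexponential GABA-A synapse. Implements the study protocols (holding
    current search, calibrated somatic test pulses, 15 ms IPSP lead, 50
    and 100 Hz spike trains, A-type density sweeps), the calcium
    inhibition statistic based on a 100 ms flux integral, action
    potential waveform metrics, a supralinearity (convexity) check, a
    synthetic two-photon line-scan generator with indicator saturation,
    noise and photoartifact correction, and an exact Wilcoxon
    matched-pairs signed-rank test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
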