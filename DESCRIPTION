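Package: ephys
Title: Intrinsic Electrophysiology Feature Extraction with Conductance-Based Synthetic Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction for whole-cell patch-clamp recordings of cortical
    neurons: passive membrane properties, voltage sag and rebound driven by the
    hyperpolarization-activated cation current (Ih), action-potential and
    spike-train features with rule-based cell classification, subthreshold
    impedance resonance from ZAP (chirp) stimulation, suprathreshold
    spike-probability densities, frequency-dependent gain and phase from frozen
    filtered-noise stimulation with spike-triggered averages, voltage-clamp Ih
    quantification with Boltzmann activation fits, and multivariate feature
    embedding. Ships a single-compartment conductance-based neuron simulator
    (leak + HCN + adaptive exponential spiking) with a quasi-active impedance
    linearization so every analysis stage can be validated against analytic
    ground truth, plus a liquid junction potential calculator based on the
    Henderson equation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    uwot,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
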