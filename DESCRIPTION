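Package: fsikir
Title: Serotonergic Kir Suppression and Gamma-Band Summation in
    Fast-Spiking Interneuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how suppression of inward-rectifier
    potassium (Kir) conductance reshapes synaptic integration in cortical
    fast-spiking interneurons (FSIs). Provides a reduced compartmental
    cable simulator (backward-Euler, Hines-ordered tree solve, Rcpp core)
    with potassium and sodium leak, an instantaneous Boltzmann Kir
    mechanism, double-exponential synapses and Ornstein-Uhlenbeck
    point-conductance background noise; calibration of conductance
    densities to measured resting potential and input resistance and of
    the neuromodulated state to the measured depolarization and input
    resistance increase; simulation protocols for conductance-reduction
    sweeps, inter-stimulus-interval summation series, noisy replicates and
    local dendritic modulation scans; an algebraic EPSP-convolution model
    of frequency-dependent temporal summation; electrophysiology trace
    analysis (decay-tau fits, ramp I-V subtraction and reversal, summation
    metrics, spike detection and filtering, inter-event-interval frequency
    bands, space-constant fits, Nernst potentials); and seeded synthetic
    data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
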