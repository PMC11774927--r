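Package: channelspectra
Title: Frequency-Domain Analysis of Voltage-Gated Ion Channel Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and frequency-domain analysis of voltage-gated
    potassium channel models under voltage clamp: the Hodgkin-Huxley n^4
    gating scheme and a three-state sequential 'p2' scheme with four
    independent rate constants.  Provides closed-form small-signal
    admittances and impedances, quadratic sinusoidal analysis (QSA) with
    non-overlapping multi-sinusoidal stimuli and frequency-averaged power
    spectra, exact Gillespie simulation of finite channel populations,
    and analytic Lorentzian fluctuation spectra derived from the channel
    autocovariance, enabling comparison of evoked linear and quadratic
    responses with spontaneous channel noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
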