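Package: neurotactile
Title: Closed-Loop Biohybrid Hand Simulation and Neurotactile Coherence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a biohybrid neuroprosthetic hand platform end to end:
    an Izhikevich-network surrogate for a cortical culture on a 60-electrode
    multielectrode array, spike-bin decoding of efferent activity into robotic
    finger taps, SA/RA mechanoreceptor encoding of fingertip forces into
    afferent stimulation, and the closed-loop (CL), afferent-deprived (AD) and
    efferent-substitution (ES) embodiment sessions built from them. Provides
    the analysis pipeline for such sessions: continuous-wavelet-transform
    power envelopes (MASP) for neurotactile event detection, inter-tap-interval
    statistics, Morlet wavelet coherence between efferent and afferent
    envelopes rendered as time-frequency images, and a compact image
    classifier that discriminates the SA and RA encodings per session.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
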