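Package: streamchains
Title: Pattern Discovery and Bistable Competition in Auditory Streaming
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the perceptual organisation of repeating tone
    sequences, such as the ABA- galloping pattern used in auditory
    streaming experiments.  A first, symbolic stage discovers repeating
    event patterns ("chains") by probabilistic inclusion and skipping of
    incoming tones; discovered chains close into predictive loops.  A
    second, dynamical stage lets the closed chains compete for perceptual
    dominance through excitatory/inhibitory rate equations driven by
    prediction successes, collisions between chains that predict the same
    event, rediscovery of the same pattern, adapting self-excitation and
    Ornstein-Uhlenbeck noise.  A readout maps chain excitations to the
    categorical percepts (integrated versus segregated) reported by human
    listeners, and analysis helpers compute first-phase choice, phase
    duration statistics, dominance proportions and the time course of the
    probability of segregation over a grid of frequency separations and
    presentation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(load = "source")
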