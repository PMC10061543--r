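Package: cisim
Title: Simulation of Psychoacoustic Experiments in Cochlear Implant Users
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end computational model of electric hearing with a
    cochlear implant. Converts audio to electrodograms under the three
    HiRes Fidelity 120 stimulation variants (sequential, paired, triplet),
    propagates stimulation through a parametric three-dimensional
    electrode-nerve interface with controllable auditory-nerve-fiber
    degeneration, simulates spike trains with a dual adaptive
    integrate-and-fire neuron population, extracts a low-rate internal
    representation, and evaluates discrimination performance with a
    whole-stimulus hidden-Markov-model back-end. Includes generators for
    spectral ripple noise and a synthetic matrix-sentence corpus, virtual
    fitting of stimulation levels, psychometric-function regression, and
    orchestration of spectral-modulation-threshold and
    speech-reception-threshold experiments at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
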