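Package: spikeEMG
Title: Spiking Neural Network Gesture Recognition for Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end myoelectric pattern-recognition toolkit built
    around a spiking neural network (SNN). Provides a synthetic generator
    for high-density (128-channel) and low-density (8-channel) surface
    electromyography recordings with electrode-shift and inter-subject
    variation; amplitude-based segmentation, FIR band-pass filtering,
    Min-Max normalisation and sliding-window sample extraction; adaptive
    temporal-contrast spike encoding; a leaky integrate-and-fire neuron
    with coupled membrane-voltage and synaptic-current decay trained by
    surrogate-gradient backpropagation through time; LDA, LSTM and CNN
    comparator classifiers; an accumulate/multiply-accumulate inference
    power model; and evaluation protocols for training-ratio,
    electrode-shift and user-independent experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
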