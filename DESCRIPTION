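Package: optoephys
Title: Simulation and Analysis of Large-Scale Micro-LED Opto-Electrophysiology Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing multi-shank silicon-probe
    recordings combined with on-shank micro-LED optogenetic stimulation.
    Generates ground-truthed synthetic sessions (spike trains, multi-site
    waveforms, local field potentials and stimulation protocols) on a
    configurable four-shank probe layout, and implements the downstream
    analyses used in hippocampal circuit studies: sharp-wave-ripple
    detection, Morlet spectrograms and current-source density, waveform
    and autocorrelogram based cell-type classification, bootstrap
    optogenetic tagging, cross-correlogram monosynaptic-connection
    inference with a convolution null, rank-order sequence readout with a
    linear decoder, and reduced device-physics solvers for light fluence,
    tissue heating and interconnect crosstalk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    e1071,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
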