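Package: thetalink
Title: Spike-Field Coupling and Coherence Analysis for Developing Prefrontal-Amygdala Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in-vivo extracellular recordings from two
    coupled brain regions: LFP conditioning (Butterworth low-pass,
    downsampling to 2 kHz, 50 Hz notch), Welch power spectral density,
    magnitude-squared coherence with a Monte-Carlo shuffle confidence limit
    and low-theta (3-5 Hz) band area under the curve, single-unit firing and
    waveform metrics with regular-spiking versus fast-spiking classification
    and cluster quality control, Morlet-wavelet spike-LFP phase locking with
    circular statistics (Rayleigh, Watson-Williams), and a normality-gated
    two-group comparison policy. A synthetic-data generator produces coupled
    two-region LFP, von Mises phase-modulated spike trains, and parametric
    spike waveforms so that every analysis stage is verifiable by
    ground-truth parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    pracma,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
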