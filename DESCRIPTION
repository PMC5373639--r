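Package: spikephase
Title: Phase Distortion of Extracellular Spike Waveforms: Simulation,
    Measurement and Correction
Version: 0.1.0
Authors@R:
    person("Analysis", "Engineering", email = "dev@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the phase response of high-pass and
    band-pass filters distorts extracellular action potential waveforms.
    Simulates ground-truth spiking signals (Poisson spike trains with an
    absolute refractory period, convolved with a biphasic spike template
    and embedded in pink 1/f noise), designs causal Butterworth
    (nonlinear-phase), symmetric FIR (linear-phase) and forward-backward
    (zero-phase) filters, quantifies waveform distortion (normalized
    Euclidean distance, SNR) and its impact on threshold-crossing spike
    detection (ROC analysis), and corrects the distortion by reversed
    refiltering of continuous or segmented recordings with several
    boundary-expansion strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
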