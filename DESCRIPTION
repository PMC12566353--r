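Package: spikechain
Title: Behavioral Simulation of Non-Linear Neural Recording Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale behavioral models of a multi-channel extracellular
    recording chain (capacitive-feedback low-noise amplifier, programmable gain
    amplifier, flash analog-to-digital converter with a perturbed reference
    ladder) with tunable non-linearity: finite gain-bandwidth, slew-rate
    limited settling, static ladder mismatch and white input-referred noise.
    Includes single-tone linearity characterization (SNR, THD, SNDR, SFDR,
    ENOB), a ground-truth spike detection and sorting pipeline (median-based
    adaptive threshold, PCA features, k-means with waveform reassignment), a
    synthetic annotated-recording generator, a Kalman-filter trajectory
    decoding paradigm, and drivers that calibrate graded distortion levels and
    sweep their impact on spike detection accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
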