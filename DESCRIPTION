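Package: circavis
Title: Circadian Analysis of Drosophila Visual Responsiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for circadian rhythms in fly
    visual electrophysiology and locomotor behaviour. Generates synthetic
    flash electroretinogram (fERG) traces, two-frequency steady-state
    visually evoked potential (SSVEP) recordings from a nonlinear cascade,
    circadian response series and Trikinetics-style activity count streams
    with known ground truth; extracts fERG features (receptor potential,
    off-transient, peak-to-peak, latency); decomposes SSVEP traces into
    harmonic and intermodulation amplitudes with noise-floor estimates;
    estimates rhythm periods by cosinor-style fits with the period as a
    free parameter (grid of candidate periods with separable linear fits,
    then nonlinear refinement); and classifies locomotor rhythmicity with
    Lomb-Scargle periodograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
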