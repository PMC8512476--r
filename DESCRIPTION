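Package: cardsobi
Title: Removal of Cardiac and Pulse Artifacts from Neonatal EEG by
    ECG-Augmented Second-Order Blind Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and removes electrical-cardiac and pulsatile
    interference from multichannel neonatal EEG recordings. The recorded
    ECG is normalized to EEG amplitude scale and an Artificial Pulse
    Signal (a saw-tooth/cosine template train locked 250 ms after each R
    peak) is synthesized; both are appended to the EEG channels before a
    square SOBI decomposition (whitening plus joint diagonalization of
    time-lagged covariance matrices). Independent components are then
    classified automatically as electrical-cardiac, pulsatile-cardiac or
    non-cardiac from Welch power-spectral-density and time-course
    correlations with the auxiliary signals and from the peak delay
    relative to the R peaks; artefactual components are removed and the
    EEG is reconstructed. Includes decomposition- and
    reconstruction-quality metrics (APICs, CC, API, SPV, varRPP,
    varPSDhr), confusion-based validation scores, a ground-truth
    synthetic neonatal EEG generator, and EDF / columnar text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
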