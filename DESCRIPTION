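Package: eegbold
Title: Comparing EEG-to-BOLD Neurovascular Transfer Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates coupled EEG-fMRI datasets with a known ground-truth
    neurovascular coupling law and compares candidate transfer functions
    from EEG spectral features to the BOLD signal: total power,
    band-limited power (frequency-response models), the root-mean-square
    frequency of the normalised spectrum (the "Heuristic") and its
    variants, and global field power.  Provides Morlet wavelet
    time-frequency decomposition, principal spatial-component projection,
    steady-state visual evoked response spectra, canonical HRF informed
    basis expansion, discrete-cosine high-pass filtering, and
    mass-univariate nested-model F-tests over separate or shared design
    matrices with Bonferroni family-wise control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
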