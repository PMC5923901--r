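Package: mrfepi
Title: Slice-Interleaved MR Fingerprinting with EPI Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative T1, T2* and proton-density mapping with
    slice-interleaved magnetic resonance fingerprinting based on a spoiled
    gradient-echo EPI readout. Provides acquisition scheduling with block-wise
    pseudo-random slice interleaving, Bloch-simulated fingerprint dictionaries
    with integrated B1+ correction, magnitude inner-product dictionary matching,
    proton-density calibration via bias-field correction and CSF normalization,
    reference relaxometry fits (inversion-recovery T1, multi-echo T2*, double-angle
    B1), digital phantoms with known ground truth, and the linearized
    noise-amplification and Monte-Carlo analyses used to choose the number of
    interleaved slices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
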