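Package: relaxmap
Title: Saturation-Recovery T1/T2 Relaxometry Mapping from Spin-Echo DICOM
    Series with GAG Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel T1 and T2 relaxation-time mapping from spin-echo
    magnitude image series acquired with the saturation-recovery method.
    Reads and writes single-frame DICOM series (variable-TR T1 protocol,
    variable-TE T2 protocol), fits mono- and bi-exponential signal models
    per pixel, masks poor fits by the coefficient of determination, and
    reports ROI statistics, line profiles and histograms. A digital
    phantom and bioreactor simulator generates DICOM input with known
    ground-truth parameter maps and Rician magnitude noise, so every
    pipeline stage is testable without scanner data. Also converts pre-
    and post-contrast T1 of cells and media into gadolinium concentration,
    Donnan fixed-charge density, and glycosaminoglycan concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    png,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
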