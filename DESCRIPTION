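Package: qctlung
Title: Quantitative CT Lung Densitometry and Low-Dose Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative computed-tomography (qCT) analysis of lung
    aeration: Hounsfield-unit compartment classification (hyperinflated,
    normally aerated, poorly aerated, nonaerated), tissue mass and volume
    computation, and 50-HU mass-frequency histograms. Includes a digital
    chest-phantom generator with a tube-current (mAs) dependent image-noise
    model for simulating paired low-dose versus reference scans,
    threshold-based lung segmentation, Bland-Altman paired-agreement
    statistics, and CT dose metrics (CTDIvol, dose-length product,
    effective dose by the DLP method), so that the effect of dose reduction
    on quantitative lung results can be studied end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
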