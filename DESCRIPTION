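Package: translocscreen
Title: Image-Based Nuclear Translocation Screening for Steroid Receptor
    Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, segmentation, quantification and statistical
    hit-calling for high-content nuclear translocation screens of
    GFP-tagged steroid receptors (glucocorticoid and androgen receptor),
    as used to detect endocrine-disrupting activity in environmental
    water samples.  Provides a synthetic micrograph generator with
    per-cell ground truth, nucleus/cytoplasm segmentation of two-channel
    fields, per-cell nuclear-to-cytoplasmic intensity ratios with QC,
    vehicle-normalized plate statistics with ANOVA-gated Dunnett
    many-to-one hit calling, dose-response summaries, and qPCR
    standard-curve relative quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
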