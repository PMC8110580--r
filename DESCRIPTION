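Package: cishscore
Title: Digital Scoring and Validation of Chromogenic RNA In Situ Hybridization Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies punctate chromogenic in situ hybridization (CISH)
    signal on brightfield histology images. Separates hematoxylin and red
    chromogen stains by optical-density deconvolution, detects nuclei by
    watershed segmentation, classifies tumor versus stroma from
    analyst-seeded example regions, counts red puncta per cell, and turns
    per-cell dot counts into the standard four-bin H-score (range 0-300)
    with control-probe quality gating and an endogenous-alkaline-phosphatase
    artifact flag. Includes a synthetic brightfield slide renderer with
    exhaustive per-cell ground truth, and a CLIA-style validation harness
    computing specificity, sensitivity, accuracy and precision with cohort
    roll-up verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    randomForest,
    pracma,
    jsonlite,
    stats,
    utils,
    tiff,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
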