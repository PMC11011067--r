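Package: erscreen
Title: Quantitative Image-Based Screening of Endoplasmic Reticulum Organisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for image-based siRNA screens of
    endoplasmic reticulum (ER) organisation in adherent cells. Quantifies,
    per cell, the areas of the polygonal regions enclosed by the peripheral
    tubular ER network and the percentage of the cytoplasm occupied by dense
    perinuclear ER, from multichannel fluorescence images (ER reporter,
    nuclear stain, plasma-membrane stain). Includes a synthetic-microscopy
    simulator with exact ground truth, seeded-watershed cell segmentation,
    INCENP multilobed-nucleus transfection QC with a plate-level efficiency
    gate, screen statistics (per-well cell sampling, one-way ANOVA with
    Dunnett many-to-one comparisons against a non-targeting control,
    star-level and direction-labelled hit calls) and -delta-Ct qPCR
    knockdown quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    multcomp,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
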