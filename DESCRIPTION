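Package: elastocad
Title: Computer-Aided Classification of Breast Strain Elastograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the hard-tissue (red) fraction inside a delineated
    breast lesion on colour strain-elastography images and classifies the
    lesion as soft, intermediate or hard. Lesion contours drawn on the B-mode
    panel are transferred to the elastogram, pixels are converted to CIELab,
    and the red region is delineated by Otsu thresholding of the a* channel
    restricted to the lesion. Includes the full observer-agreement and
    diagnostic-performance battery (Jaccard/under-/over-segmentation of masks,
    Cohen's kappa with interpretive bands, ICC, sensitivity/specificity,
    Mann-Whitney AUC with stratified bootstrap confidence intervals and paired
    AUC-difference tests) and a synthetic phantom generator with known ground
    truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    tiff,
    tools,
    withr
Suggests:
    e1071,
    farver,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
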