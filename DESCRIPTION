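Package: recurtma
Title: Early Breast Cancer Recurrence Prediction from Tissue Microarray Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for predicting early (within three years)
    breast cancer recurrence from hematoxylin and eosin stained tissue
    microarray core images. Provides a synthetic cohort and feature
    generator calibrated to the within- and between-patient cosine
    similarity structure of transfer-learning image embeddings, age-matched
    balanced case-control construction, convolutional feature extraction
    with spatial mean pooling under a pluggable extractor contract, a
    maximum-margin linear classifier over patient-level feature vectors,
    cross-patient and within-patient validation schemes, binomial
    normal-approximation confidence intervals, Kaplan-Meier and Cox
    proportional hazards time-to-event analysis, and relative frequency
    differences (identity-link binomial GLM) between image-based and
    genomic risk-of-recurrence classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    survival,
    jsonlite,
    stats,
    utils,
    tools,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
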