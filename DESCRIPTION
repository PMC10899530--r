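Package: ktrq
Title: Single-Cell ERK Reporter Quantification and Fluorescent Histology Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying ERK pathway activity from kinase
    translocation reporter (KTR) live-cell imaging and for measuring
    metastatic burden from fluorescent histology. Provides synthetic-data
    generators with exact ground truth (single-cell activity trace
    ensembles, two-channel time-lapse movies, three-channel tissue
    sections), nuclear segmentation and cell tracking, cytoplasm-to-nucleus
    ratio trace extraction, MEK-inhibitor floor normalization, per-cell
    responder calling by paired t-test with amplitude and area-under-curve
    features, dose-response summaries, response-class assignment, tumor
    burden and 90th-percentile marker quantification, Bland-Altman method
    agreement, and small reporting statistics (fold change, percent
    survival, Benjamini-Hochberg adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
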