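Package: ctcfloops
Title: CTCF Chromatin Loop Prediction and Cross-Condition Discordance Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts CTCF-mediated chromatin loops from genomic and
    epigenomic features. Reads ChIA-PET/Hi-C loop calls (bedpe), ENCODE
    narrowPeak tracks, FIMO motif hits and GTF gene models; builds anchor
    and interloop windows; labels high-confidence loops by convergent
    CTCF motif orientation, CTCF occupancy and RAD21 colocalization;
    trains a gradient-boosted loop classifier and an auxiliary
    random-forest CTCF-binding predictor on binned epigenomic tracks;
    and scores discordant (lost/gained) loops between control and case
    conditions, annotating and ranking the genes they span. Ships a
    synthetic-fixture generator with a planted feature-to-loop
    dependency so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    ranger,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
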