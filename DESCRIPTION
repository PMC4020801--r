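Package: cemspep
Title: Label-Free CE-MS Peptidomics from Peak Lists to Differential Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidy pipeline for label-free bottom-up peptidomics by capillary
    electrophoresis coupled to mass spectrometry (CE-MS): robust noise
    estimation and charge-state deconvolution of per-sample peak lists into
    neutral-mass features, migration-time and mass calibration by linear
    regression on high-frequency reference features, internal-standard
    intensity normalization, tolerance-based cross-sample consensus peptide
    matching, in-silico tryptic annotation against a FASTA database with
    charge-aware disambiguation, and protein-level differential abundance
    statistics with Benjamini-Hochberg false discovery rate control. Includes
    a ground-truth synthetic cohort generator so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
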