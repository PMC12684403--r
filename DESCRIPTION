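Package: chimbench
Title: Benchmarking De Novo Chimera Detection on Long-Read ITS Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for benchmarking de novo chimera
    detection on long-read (full-ITS) amplicon data. Generates ground-truth
    communities of ITS1-5.8S-ITS2 templates with PacBio-like sequencing
    errors, plants PCR chimeras (region-weighted breakpoints, two or three
    parents, optional reverse-complement segments) and library-preparation
    concatemers, runs a parameterized UCHIME-style vote-scoring detector,
    scores detection with precision/recall/F1 over parameter-grid sweeps,
    and applies secondary validation rules: alignment-based false-positive
    rescue, split-HSP false-negative flagging, and 5.8S-multiplicity
    concatemer scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
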