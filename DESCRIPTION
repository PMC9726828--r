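Package: crmscreen
Title: Top-Regulator Screening and Cis-Regulatory Module Calling from
    Transcription-Factor Binding Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers cell-type-specific candidate regulator transcription
    factors and candidate cis-regulatory modules (CRM) from per-TF ChIP-seq
    binding-region sets and a small foreground gene set. Binding regions are
    converted to distance-decayed regulatory-potential scores around each
    gene's transcription start site, thresholded by per-TF empirical p-values
    into a binary TF-target matrix, and screened for foreground-versus-
    background discrimination over many random background gene sets; replicate
    screens are combined by rank-product meta-analysis with a permutation null
    and Benjamini-Hochberg false-discovery-rate control. Clusters of the
    selected regulators' binding regions near foreground transcription start
    sites are then called as candidate CRM, optionally filtered by overlap
    with evidence interval tracks such as open chromatin or conservation. A
    synthetic-data generator with planted regulator enrichment makes every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
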