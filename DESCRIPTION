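Package: chardyn
Title: Chromatin-Accessible Region Dynamics Across the Th17-to-Th1 Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies chromatin-accessible regions (ChARs) from ATAC-seq
    peak-level counts by differential accessibility between pathogenic and
    regulatory Th17, annotates them to nearest transcription start sites,
    filters by evolutionary conservation, integrates RNA-seq expression
    concordance, assigns a six-mode opening/closing temporal taxonomy across
    the two-step regulatory Th17 to pathogenic Th17 to Th1 conversion, and
    ranks transcription-factor motifs by their appearance in opening versus
    closing regions. Ships a fully specified synthetic-data generator with
    planted ground truth so the whole pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    withr,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
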