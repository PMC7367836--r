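Package: fragsig
Title: Multi-Omic Fragility Signatures from Replication Timing, Transcription
    and Chromatin Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects replication-stress-induced replication timing (RT)
    changes from early/late S-phase Repli-seq counts, quantifies nascent
    transcription from Bru-seq-style read counts, calls topologically
    associating domain (TAD) boundaries from contact matrices via a
    diamond insulation (TAD-separation) score, and combines the layers
    into a gene-level chromosomal fragility signature: a TAD boundary
    overlapping a highly transcribed large gene whose replication is
    delayed under mild aphidicolin stress. Candidate core fragility
    regions are localized by the characteristic V-shaped RT-delay
    profile. Ships a fully specified synthetic-data generator with
    planted ground truth so every stage is testable without external
    downloads.
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
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
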