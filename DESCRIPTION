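Package: ubiscreen
Title: Integrated Proteomic and Transcriptomic Screening for E3 Ubiquitin
    Ligase Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for nominating candidate substrates of SCF-type E3
    ubiquitin ligases from label-free shotgun proteomics of a ligase mutant
    versus wild type. Implements spectral-counting normalization of MudPIT
    run reports against in-silico tryptic peptide counts, replicate merging
    and overlap partitioning under a local-FDR filter, mutant-only and
    mutant-higher protein classification, a transcript-level exclusion
    filter based on microarray differential expression, and downstream
    promoter hexamer enrichment (binomial statistics) and GO
    overrepresentation (Fisher's exact test). A synthetic-data module
    generates proteomes, run reports, expression matrices and promoter sets
    with planted signal so the whole screen is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
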