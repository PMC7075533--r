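Package: airrbench
Title: Benchmarking Analytics for Antibody Repertoire Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical machinery for benchmarking immunoglobulin heavy-chain
    repertoire annotation: germline reference set comparison at four naming
    levels and change-history tabulation, harmonization and preprocessing of
    AIRR Rearrangement tables, V/D/J gene mishit metrics against known ground
    truth, multi-tool unique-CDR3 overlap partitions, and CDR3 similarity
    networks (Levenshtein distance one) with shared sub-network degree
    analysis. Includes a synthetic-data module that emulates simulator-style
    repertoires (diverse and polarized compositions), annotator outputs with
    configurable error structure, and germline change logs, so the full
    benchmark runs end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    jsonlite,
    withr,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
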