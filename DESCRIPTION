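Package: cpdrepair
Title: Genome-Wide Analysis of Photolyase and Excision Repair of UV-Induced
    CPD Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-nucleotide mapping of UV-induced cyclobutane
    pyrimidine dimers (CPDs) from CPD-seq sequencing reads, alkaline-gel
    anchored normalization of repair fractions, and repair profiling across
    gene bodies, nucleosomes and transcription-factor binding sites, together
    with strand-resolved analysis of UV mutation spectra and transcriptional
    asymmetry. Includes a synthetic-data module that emulates the damage,
    repair, gel and mutation-accumulation experiments so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
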