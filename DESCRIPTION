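Package: genemx
Title: Gene-by-Descriptor Heat-Matrix Curation and Missing-Protein Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for chromosome-centric proteome curation:
    a genes-by-descriptors heat matrix with versioned snapshots and diffing,
    quantized colour coding of descriptor values, the sort-and-select triage
    workflow for missing proteins (SRM/shotgun/transcriptome evidence),
    splice-isoform and guilt-by-association target selection, peptide
    susceptibility ranking, TSV/JSON readers and writers with quarantine
    validation, and a seeded synthetic chromosome generator so every analysis
    is testable fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
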