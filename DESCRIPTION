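Package: ppiscreen
Title: Comparative Protein-Protein Interaction Screening Across Species
    and Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for colony-array protein-fragment
    complementation (DHFR-PCA) screens that compare protein-protein
    interaction networks between two yeast species and their reciprocal
    F1 hybrids. Covers cross design and testability accounting, gridded
    plate-image quantification, signal-index scoring with per-strain
    mating-type bias correction, threshold-based interaction calling
    against an among-complex null, residual-based detection of gained and
    lost interactions, alignment-based lineage-specific divergence
    profiling, and a synthetic-screen generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
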