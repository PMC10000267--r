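Package: acpforge
Title: In Silico Anticancer Peptide Screening from Sliding-Window Protein Libraries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering anticancer peptide (ACP) candidates from a
    source protein: exhaustive sliding-window peptide library generation from
    FASTA, residue-based net-charge annotation, secondary-structure handling
    with a propensity-based surrogate annotator, geometric-mean consensus
    scoring of external ACP classifier probabilities, candidate ranking with
    redundancy collapse, plate-assay quantification (MTT viability, hemolysis,
    autophagy activity, interpolated IC50), and a label-free SWATH/DIA
    differential-expression stage (log2, normalization, median imputation,
    per-protein t-tests, fold-change/p filtering). Seeded synthetic-data
    generators make every stage testable without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
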