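Package: mitescan
Title: Structure-Based Detection of Miniature Inverted-Repeat Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects miniature inverted-repeat transposable elements (MITEs)
    in eukaryotic genome sequences from structure alone. Chromosomes are cut
    into overlapping fragments, a k-mer hash index is used to enumerate
    terminal-inverted-repeat (TIR) seed pairs with at most one interior
    mismatch, seeds are merged into maximal TIR candidates, candidates are
    validated by their target-site duplication (TSD), scored with a trained
    6-mer log2 likelihood-ratio model, screened for segmental-duplication
    artifacts by flanking-sequence similarity, and clustered into families on
    a sequence-similarity network with one representative per family and a
    TSD-based superfamily label. A seeded synthetic-genome generator with a
    machine-readable truth table supports end-to-end validation without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
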