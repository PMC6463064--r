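Package: endosym
Title: Tissue-Resolved Metatranscriptomics of a Bacterial Endosymbiont
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing the transcriptome of a low-titre bacterial
    endosymbiont across host tissues from a per-gene read-count matrix.
    Implements TPM quantification from counts and gene lengths, replicate-based
    presence calls and the multi-tissue core transcriptome, housekeeping-scaled
    per-gene read ratios with rank and up-regulation calls, and a TMM-normalized
    nonparametric differential-expression stage that contrasts between-tissue
    signal against a within-tissue replicate noise distribution. A seeded
    negative-binomial count simulator with tissue-specific symbiont titres,
    titre-invariant housekeeping genes and spiked fold changes provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
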