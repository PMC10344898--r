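Package: pegforge
Title: Modeling Determinants of Prime Editing Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the chromatin and sequence determinants of
    prime editor (PE2) efficiency. Includes a synthetic-data generator with
    planted effects, edit-percentage quantification from classified amplicon
    reads, a Hamming-distance NGG off-target scanner, SVD-based consensus
    enrichment calling for IP/input ChIP-seq tracks with a logistic
    editability classifier, nearest-neighbor RNA-DNA hybridization free
    energies for pegRNA primer-binding sites, stepwise last-templated-
    nucleotide regression across RT template lengths, per-design elastic-net
    sequence models, a position-specific-filter neural network, and
    simulated-annealing plus maximum-entropy interpretation of trained
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    glmnet,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
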