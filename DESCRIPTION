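Package: riboPause
Title: Codon-Resolution Ribosome and Disome Profiling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for codon-resolution analysis of ribosome and disome
    (collided-ribosome) profiling data: A-site offset assignment and
    metagene profiles, per-codon pause and vulnerability scores, read-based
    codon decoding-speed ratios, P/A-site di-codon pause matrices,
    collision and queue geometry detection around codons of interest, and
    gene-level disome-enrichment interaction testing for classifying
    targets of ribosome-associated quality control.  A synthetic footprint
    simulator encoding the ribosome stalling, queueing and termination
    geometry makes every pipeline stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
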