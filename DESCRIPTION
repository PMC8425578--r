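Package: fastqflow
Title: Empirical Quality Filtering of Short-Read Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modular preprocessing of Illumina-style FASTQ data with an emphasis on
    empirical, library-design-driven quality control. Provides positional
    nucleotide and Q-score summaries, fixed and quality-window read trimming,
    ambiguity-safe dual-barcode demultiplexing with staged Hamming-distance
    passes, restriction-motif filtering of read starts, k-mer offset-voting
    adapter detection and removal with an optional local-alignment fallback,
    whole-read Q-score composition filtering, read-compression and empirical
    barcode error-rate metrics, and a reduced-representation sequencing
    simulator with full per-read ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
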