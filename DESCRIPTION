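Package: pirnascreen
Title: Screening piRNA Databases for Non-Coding RNA Fragment Contaminants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects piRNA-sized fragments of structural non-coding RNAs
    (rRNA, tRNA, YRNA, snRNA, snoRNA, miRNA precursors) that are
    mis-annotated as PIWI-interacting RNAs in piRNA sequence databases.
    Implements mismatch-tolerant ungapped matching with a 19-nt seed index
    and an exhaustive brute-force oracle, positional nucleotide composition
    statistics (5' uridine and position-10 adenine bias), length-distribution
    comparisons, a ratio-of-ratios enrichment score over two-way sequence
    partitions with a hypergeometric overlap test, abundance-threshold
    contamination summaries, and a seed-reproducible synthetic small-RNA
    database generator with a ground-truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
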