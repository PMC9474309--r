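Package: ssrscan
Title: Boyer-Moore Scanning of Simple Sequence Repeats with ANOVA-Based
    Genome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans genome sequences for fixed simple-sequence-repeat (SSR)
    motifs with a Boyer-Moore exact matcher (first-occurrence,
    bad-character and good-suffix heuristics), summarizes tandem runs and
    occurrence counts, and compares SSR abundance across genomes and
    motifs with one-way and two-way ANOVA plus Tukey HSD all-pairs
    comparisons built from the sum-of-squares decomposition. Includes a
    synthetic-genome generator with planted repeats and exact truth
    tables, windowed count matrices as ANOVA observation units, BED/TSV
    writers, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
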