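Package: shufflonr
Title: Shufflon Conformation Enumeration and pilV Variant Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing shufflon multiple-DNA-inversion systems of
    I-complex conjugative plasmids. Models the invertible-cassette locus as a
    signed permutation, enumerates all conformations reachable by
    Rci-mediated block inversions, detects sfx recombination sites by motif
    scan, builds per-variant junction signatures (39-bp footprints spanning
    the pilV 3' constant end and the adjacent cassette), counts them directly
    in FASTQ reads to quantify pilV variant frequencies, and computes
    donor-versus-transconjugant enrichment and conjugation frequencies with
    limit-of-detection censoring. Includes a fully seeded synthetic-data
    layer: locus generation, per-cell inversion dynamics, transfer selection,
    and substitution-error read simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
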