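Package: cas3design
Title: Spacer and Cloning-Construct Design for Compact Type I-C CRISPR-Cas3
    Genome Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design toolkit for plasmid-based type I-C CASCADE-Cas3 genome
    engineering in high-GC bacteria such as streptomycetes. Scans genomes for
    5'-TTC-3' protospacer adjacent motifs (PAMs) on both strands, performs
    genome-wide PAM censuses (including the Cas9 5'-NGG-3' comparison),
    extracts fixed-length protospacer candidates from a target region, and
    evaluates their off-target landscape by exact whole-length counting,
    PAM-dependent seed counting, and mismatch-tolerant search. Also designs
    the cloning side: four-primer Gibson-assembly spacer cloning with an
    in-silico assembly verifier, restriction digestion, and repair-template
    (homology arm with optional cargo) design with restriction-site screening
    and a predicted edited locus. Includes a seeded synthetic-genome generator
    with site planting so every analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    methods,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
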