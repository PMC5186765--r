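Package: orphancore
Title: Discovery and Exploitation of Taxonomically Restricted Core Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for discovering gene
    families that are part of the core genome of a bacterial genus yet have no
    detectable homolog outside it (orphan, or taxonomically restricted, core
    genes), characterizing them (Nei-Gojobori Ka/Ks with Jukes-Cantor
    correction, isoelectric point, molecular weight, hydropathy-based
    transmembrane segments, position relative to the replication origin), and
    exploiting them as concatenated nucleotide probes for species phylotyping
    and as protein probes for translated screening of metagenomes and
    metatranscriptomes. Homology decisions use exact Smith-Waterman and
    Needleman-Wunsch alignment with Karlin-Altschul E-values, reciprocal
    best-hit clustering, and single-linkage family construction. Alignment-free
    genome relatedness is provided through tetranucleotide z-score signatures
    and BLAST-based average nucleotide identity. A seeded synthetic pan-genome
    generator with truth tables makes the whole pipeline testable without any
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    igraph,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
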