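Package: b1hscan
Title: Deep Mutational Scanning of Protein-DNA Specificity from Bacterial
    One-Hybrid Selections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for deep mutational scanning of the four
    DNA-binding specificity residues of the chromosome-segregation protein
    ParB, assayed by bacterial one-hybrid (B1H) selection against the parS
    and NBS operator sites. Converts staggered-amplicon FASTQ reads from an
    NNS-randomised library into per-variant counts, computes log10 enrichment
    fitness scores anchored to the two wild-type proteins (ParB RTAG, Noc
    QKKR), assigns specificity classes, builds sequence-space networks of
    functional variants under amino-acid or nucleotide-substitution adjacency,
    enumerates shortest mutational paths to the NBS-specific wild type with an
    edge-shuffled random-graph null, and clusters protein-by-DNA-site
    dissociation-constant matrices. Includes a synthetic-data generator with a
    ground-truth fitness landscape so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
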