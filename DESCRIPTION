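Package: toxscan
Title: Discovery and Characterization of Polymorphic Toxin Effectors from
    Annotated Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for discovering
    polymorphic toxin effectors anchored on marker domains (FIX-like) and
    nuclease toxin domains (PoNe-like) in annotated bacterial proteomes.
    Implements pseudocounted position-specific scoring matrices with an
    iterative, capped homology search calibrated against decoy proteomes;
    the post-search curation rules (E-value and length thresholds,
    contig-end removal, multi-contig deduplication); CD-HIT-style greedy
    incremental clustering of domain-flanking sequences; strand-aware
    genomic neighborhood analysis including effector/immunity pairing and
    domain-architecture classification; type VI secretion system (T6SS)
    core-component genome classification; sequence-logo information
    content and consensus-motif extraction; and neighbor-joining
    phylogenies under the Jukes-Cantor model. A seeded synthetic-genome
    generator with planted domain families and ground-truth tables makes
    every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    withr,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
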