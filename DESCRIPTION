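Package: mutatorscan
Title: Hypermutator Detection and Phylogeography from Near-Identical
    Bacterial Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for characterizing bacterial
    hypermutator lineages diverging in culture collections. Calls and
    normalizes variants between near-identical assembled genomes,
    applies coverage/quality filters, annotates coding consequences,
    computes six-class mutational spectra and indel/SNP ratios, infers
    mismatch-repair and oxidized-guanine-repair mutator signatures,
    estimates an expected-versus-observed Ka/Ks statistic by exhaustive
    coding-site enumeration, performs ad hoc core-genome MLST allele
    calling with UPGMA and average-linkage Manhattan clustering,
    screens antimutator gene panels, detects convergent
    resistance-associated mutations in squatter colonies, and includes
    a forward genome-evolution simulator with ground-truth variant
    sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
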