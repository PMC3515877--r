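Package: mapkevol
Title: Molecular Evolution of the Plant MAPK Gene Family
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for the molecular evolution of a plant gene
    family (the mitogen-activated protein kinases, MAPKs): identification of
    family members in proteomes by position-specific scoring profiles and
    activation-loop (TxY) motif classification, between-species Ka/Ks by
    Nei-Gojobori codon counting with Jukes-Cantor correction, within-population
    nucleotide diversity partitioned into synonymous and nonsynonymous sites
    from per-accession variant tables via pseudochromosome construction,
    sliding-window divergence and polymorphism scans, distance-based phylogenies
    (neighbor joining, UPGMA, bootstrap support) and coexpression dendrograms,
    and family-versus-background selection tests. All inputs can be generated
    by a built-in synthetic-data module with recorded ground truth, so every
    stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
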