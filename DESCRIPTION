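Package: natminer
Title: Desk-Scale Mining and Annotation of Microbial Arylamine
    N-Acetyltransferase Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for surveying microbial genomes for
    arylamine N-acetyltransferase (NAT) genes. Implements translated
    six-frame homology search with affine-gap local alignment and
    Karlin-Altschul E-values, motif-based family annotation with
    catalytic-triad (Cys-His-Asp) verification, frameshift pseudogene
    reconstruction, biosynthetic gene cluster (BGC) context analysis with
    flank extraction and protocluster membership, sequence similarity
    networks, neighbor-joining phylogenies with bootstrap support,
    plasmid screening at relaxed identity thresholds, GC-deviation
    genomic-island detection, and survey aggregation. A seeded synthetic
    genome generator implants NAT-like loci (intact, frameshifted or
    truncated), BGC-like neighborhoods and low-GC islands with exact
    ground-truth manifests, so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
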