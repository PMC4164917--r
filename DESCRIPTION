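Package: sagphage
Title: Viral Detection and Virus-Host Ecology in Single-Cell Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects viral contigs in single-cell amplified genome (SAG)
    assemblies using hallmark-gene annotation, guilt-by-association protein
    similarity, virome read support, and reference-free gene-architecture
    metrics; annotates remnants of past infections (CRISPR repeat-spacer
    arrays, defective prophages); classifies viral presence in metagenomes by
    fragment recruitment and computes normalized abundances and virus-to-host
    ratios; clusters phage genomes into genera by shared gene content and
    tests co-infection association. Includes a fully seeded synthetic-data
    generator that produces SAG assemblies, planted infections and metagenome
    read sets with machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
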