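Package: mosaicAncestry
Title: Ancestry Painting and Phylogenetic Concordance for Mosaic Mouse Chromosomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the subspecies origin of a chromosome from a
    chromosome-substitution (consomic) mouse strain. Implements quality
    filtering and novelty classification of SNP/indel calls, a simplified
    functional-consequence annotator against gene models, consensus-based
    windowed sequence-similarity painting of the focal chromosome against
    subspecies representative strains, and locus-wise neighbor-joining
    tree-topology concordance with bootstrap support. A synthetic
    mosaic-chromosome generator with ground-truth introgression tracts
    supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SNP, VariantAnnotation, Phylogenetics, Sequencing
RoxygenNote: 7.3.3
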