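Package: coexNeighbors
Title: Co-Expression of Chromosomally Neighbouring Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts and classifies pairs of chromosomally neighbouring
    genes from a genome annotation (divergent, uni-directional, convergent;
    overlap taxonomy on opposing strands), computes their co-expression
    (Pearson correlation of log2 expression vectors across experiments)
    against a random-pair background, profiles co-expression by intervening
    genes and by intergenic distance, and decomposes the co-expression of
    close neighbours into a shared-chromatin component, a bi-directional
    shared-promoter component, and a transcriptional-interference component.
    Includes a latent-factor simulator of annotation plus expression data
    with closed-form expected pair correlations, so the full pipeline can be
    validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Coverage, Annotation
RoxygenNote: 7.3.3
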