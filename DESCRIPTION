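Package: heatscreen
Title: Heat-Stress Transcriptomics Screening Toolkit for Tag-Count and
    Read-Count Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the computational screen used to discover
    heat-responsive DREB transcription factors in tomato: an exact
    Poisson test for two-library digital gene expression (tag counts),
    Benjamini-Hochberg false-discovery-rate control and fold-change
    candidate screening, RPKM and median-of-ratios normalisation of
    multi-sample count matrices, hypergeometric pathway
    over-representation, sequence-level screens (CDS translation,
    single-AP2-domain filtering by iterated local alignment,
    strand-aware promoter extraction, DRE/CRT cis-element scanning,
    tandem bait construction), neighbor-joining phylogeny with
    bootstrap support, 2^-ddCt relative quantification and the heat
    injury index. A synthetic-data layer generates every input with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    ape,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
biocViews: GeneExpression, DifferentialExpression, Transcriptomics,
    SequenceMatching, Phylogenetics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
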