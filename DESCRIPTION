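Package: plantsrna
Title: Plant Small RNA Sequencing: miRNA Discovery, Classification,
    Differential Expression and Target Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a plant
    small-RNA sequencing analysis pipeline: adaptor trimming and read
    filtering, collapsing to unique tags, removal of annotated
    non-miRNA small RNAs, seed-and-verify ungapped genome mapping,
    hairpin precursor discovery under an explicit secondary-structure
    energy model with MFE/MFEI filtering and 5p/3p duplex detection,
    classification of mature sequences as conserved, variant or novel
    against a reference mature-miRNA catalogue, median-of-ratios count
    normalization with a fixed-dispersion negative-binomial exact test
    for differential expression, and complementarity-based miRNA
    target scanning on transcripts.  A synthetic-data module generates
    genomes with planted MIR and ncRNA loci plus simulated libraries
    with known ground truth, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, DifferentialExpression, GenePrediction
RoxygenNote: 7.3.3
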