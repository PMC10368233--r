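Package: chiaNet
Title: Predicting ChIA-PET Chromatin Interactions from Hi-C and ChIP-seq
    with a Dilated Residual Convolutional Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pixel-level prediction of protein-mediated ChIA-PET chromatin
    interactions on binned contact maps. Takes KR-normalized Hi-C contact
    matrices and ChIP-seq coverage tracks, assembles three-channel tiles along
    the matrix diagonal, and scores every pixel with a dilated residual
    convolutional network trained under a leave-one-chromosome-out protocol.
    Includes readers for Juicer-dump triplet text, dense matrix text, bedGraph
    and BEDPE; ChIA-PET anchor-to-pixel labeling; tiled inference with
    overlap averaging and symmetrization; the imbalanced evaluation protocol
    (sampled negative sets, average precision, ROC-AUC, precision-recall
    curves, top-N accuracy) with a ChIP-seq inner-product baseline and
    shuffle controls; and a seeded generator of coupled synthetic
    Hi-C/ChIP-seq/ChIA-PET chromosomes with planted loops so the whole
    pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    tools,
    methods,
    stats,
    utils,
    data.table,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, HiC, FunctionalGenomics, Classification, Software
RoxygenNote: 7.3.3
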