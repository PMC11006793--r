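Package: smorfcp
Title: Coding-Potential Modelling and Genome Scanning for Small Open Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds species-specific coding-potential classifiers for small
    open reading frames (smORFs, at most 101 codons including the stop) from
    positive mRNA CDS and negative ncRNA ORF sequence sets. Sequences carry
    their three upstream nucleotides so that translation-initiation-site
    (Kozak-context) nucleotide bias can be scored alongside in-frame features
    (codon usage bias, hexamer log-likelihood score, Fickett position
    parameters) and continuous/discontinuous k-mers. Provides feature ablation
    and mRMR-IFS feature selection, 10-fold cross-validated model comparison
    (logistic regression, SVM, random forest, gradient tree boosting),
    precision-targeted score cutoff calibration per start codon, and a
    six-frame genome scanner for smORFs with ATG and near-cognate (non-ATG)
    start codons that emits a filtered smORF database (FASTA, BED6, TSV).
    Synthetic data generators make the whole pipeline testable without any
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    e1071,
    xgboost,
    jsonlite,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
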