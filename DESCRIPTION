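Package: carnafold
Title: Chromatin Contact Map Prediction from DNA Sequence and
    Chromatin-Associated RNA Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how chromatin-associated RNAs (caRNAs) relate to
    3D genome folding. Converts DNA-DNA contact pairs into normalized,
    smoothed log observed-over-expected target maps at 2048-bp resolution;
    engineers per-bin caRNA feature tracks from RNA-DNA interaction pairs
    (nascent transcription and trans-located signal split into eight RNA
    classes) plus accessibility and expression channels; and fits a
    convolutional neural network that predicts ~1 Mb contact maps from DNA
    sequence together with the feature channels, trained to maximize
    Pearson correlation with the experimental maps. Includes map-comparison
    metrics (MSE, Pearson, Spearman, stratum-adjusted correlation, SSIM),
    insulation profiling and TAD-boundary classification, feature
    attribution scores with enrichment analysis, hypergeometric
    candidate-RNA statistics, in-silico CTCF-motif insertion and
    caRNA-elevation perturbation experiments, and a local-alignment scan
    for trans R-loop candidates. A synthetic-data generator with planted
    TADs, loops, RNA-DNA contacts and sequence homologies makes the whole
    pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    Rcpp,
    data.table,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
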