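Package: methbind
Title: Predicting In Vivo Transcription Factor Binding from Base-Resolution
    DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised prediction of in vivo transcription factor (TF)
    binding at motif-derived candidate sites from whole-genome bisulfite
    sequencing counts. Methylation counts in a window layout centred on each
    candidate motif are modelled with beta-binomial distributions fitted
    separately for bound and background sites by the method of moments; the
    per-site log likelihood ratio between the two models is a methylation
    score that is combined with static genomic features (motif score,
    conservation, distance to TSS, annotation overlaps) in a random-forest
    classifier with vote-fraction probabilities and Gini importance.
    Includes a PWM genome scanner for candidate selection, ROC/PR
    evaluation, and a synthetic-data generator emulating the hypomethylation
    dip at bound sites so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
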