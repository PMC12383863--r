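Package: cpgmix
Title: Targeted Bisulfite Amplicon Methylation Calling and Model-Based
    Clustering of Psychopathology Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses targeted bisulfite amplicon sequencing
    experiments linked to adolescent psychopathology cohorts. Provides a
    seeded generator for synthetic cohorts (bivariate CBCL T-scores from a
    Gaussian mixture, binary risk indicators, per-CpG methylation
    percentages) and for bisulfite-converted paired-end amplicon reads with
    known ground truth; a bisulfite-aware affine-gap Smith-Waterman aligner
    with coherent-pair retention, per-CpG base-frequency tallying, C-to-T
    methylation percentages and conversion-efficiency/coverage QC;
    constrained-covariance Gaussian finite mixture models (EII, VII, EEI)
    fitted by EM with mclust-convention BIC model selection; and
    cluster-characterization statistics (Welch/pooled t, Yates chi-square,
    phi, Cohen's d, Bonferroni correction) with random hot-deck imputation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
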