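Package: ntermflow
Title: N-Terminome Annotation and Quantitative Proteomics Differential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for positional annotation of protein N-termini
    against predicted transit- and signal-peptide cleavage sites, dimethyl
    isotope-labeling mass accounting, empirical-Bayes moderated t-tests for
    N-terminal peptide abundance, label-free proteome differential analysis
    (quantifiability filtering, downshifted-Gaussian imputation, ANOVA with
    Benjamini-Hochberg FDR and Tukey HSD post-hoc, z-score hierarchical
    clustering, PCA), and stringent filtering of affinity-purification
    mass-spectrometry interactor candidates. Ships a synthetic-data module
    that simulates terminome, proteome and pull-down experiments with ground
    truth, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    withr
Suggests:
    limma,
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
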