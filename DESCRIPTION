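Package: ihtnet
Title: Integrated Permutation-Based Differential Expression and
    Transcription-Factor Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing tumor transcriptomes between two patient
    groups with an integrated hypothesis-testing approach: per-gene Welch t,
    rank-sum and log2-median-ratio statistics against a label-permutation
    null, Stouffer combination of the three empirical p-values, Storey
    q-value multiple-testing correction, and a permutation-derived
    log2-median-ratio effect-size cutoff.  Downstream stages cover preranked
    gene-set enrichment with a Kolmogorov-Smirnov running-sum score,
    resampling-based master-regulator discovery over transcription-factor
    regulons, Z-score transcription-factor and network activity scoring with
    stratified group comparisons, and construction and export of a
    co-regulation network model.  A synthetic cohort generator with planted
    differential genes and differential TF activities makes the whole
    pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
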