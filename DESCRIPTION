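Package: connstrat
Title: Behavioural Consensus Clustering and Network Based Statistic
    Inference for Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify study participants into data-driven
    behavioural subgroups by subsampled consensus clustering over
    affinity-kernel similarity networks, and to test group differences in
    resting-state functional connectomes with the Network Based Statistic
    (edgewise linear models, supra-threshold component extraction and
    max-statistic permutation control of the family-wise error rate).
    Includes construction of thresholded Fisher-z connectivity matrices
    from regional time series, within/between intrinsic-network component
    summaries, Sorensen-Dice and hypergeometric overlap statistics between
    components, rank-based behavioural group comparisons with
    covariate-adjusted permutation tests, and synthetic cohort generators
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
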