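Package: heteromix
Title: Finite Mixture Models for Clustering Heterogeneous Biological Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimation of finite mixture models for mixed discrete and
    continuous data by the expectation-maximization (EM) algorithm, aimed
    at model-based clustering of biological sequences, expression profiles
    and phenotype tables.  Components are naive-Bayes products of
    per-feature Gaussian, discrete or exponential distributions; beyond
    the standard model the package provides context-specific independence
    (CSI) mixtures learned by structural EM with automatic component
    merging, mixtures of dependence trees whose topology is re-estimated
    per component by a maximum-weight spanning tree on mutual information,
    and semi-supervised estimation from partial hard labels or soft
    pairwise positive/negative constraints.  Includes FASTA and delimited
    table ingestion with missing-value support, model simulation,
    posterior classification with an entropy cutoff, feature-relevance
    ranking, model serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
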