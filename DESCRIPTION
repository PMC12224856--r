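Package: demuxEnsemble
Title: Accuracy-Weighted Ensemble Genetic Demultiplexing for Pooled scRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combines the per-cell outputs of four genetic demultiplexing tools
    (Demuxalot, Demuxlet/Freemuxlet, Souporcell, Vireo) into ensemble donor
    assignments for pooled single-cell RNA-seq. Implements an unsupervised
    accuracy-weighted probabilistic ensemble in which each tool's class
    probabilities are weighted by its balanced accuracy estimated against a
    leave-one-tool-out consensus proxy; a graph-based doublet detection step
    that percentile-ranks doublet-related features, screens for confident
    doublets, and selects nearest-neighbour parameters by a kurtosis-driven
    sweep; an ensemble-independent doublet rescue from high-specificity tools;
    and a per-cell singlet assignment confidence score. Also provides parsers
    for the native output formats of the constituent tools, a full suite of
    classifier evaluation metrics (ARI, balanced accuracy, MCC, empirical AUC,
    usable-cell yield), and a synthetic generator of ground-truth-labelled
    constituent-tool outputs for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
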