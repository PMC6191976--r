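Package: hopnet
Title: Cost-Sensitive Hopfield Networks for Node Label Prediction on
    Sparse Biological Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised binary node classification on sparse weighted
    undirected graphs (e.g. protein functional networks) with a parametric
    discrete Hopfield network whose activation values are learned to
    counteract strong class imbalance.  The asynchronous dynamics is
    parallelized by partitioning nodes into independent sets via iterated
    Luby maximal-independent-set extraction (a greedy graph coloring);
    updating one color class at a time provably reproduces the sequential
    asynchronous attractor.  Includes symmetric degree normalization,
    edge-list and Matrix Market readers, an Erdos-Renyi benchmark
    generator with unbalanced planted labelings, a stratified
    cross-validation harness with precision/recall/F and AUPRC, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    parallel,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
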