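Package: graphxgen
Title: Synthetic Graph Benchmarks with Ground-Truth Explanations for GNN Explainability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates seeded synthetic node-classification graphs with
    planted motifs and per-node ground-truth explanation masks (nodes,
    node features, edges), for benchmarking explainers of graph neural
    networks. Provides five evaluation metrics for predicted explanations
    (accuracy, unfaithfulness, instability, counterfactual-fairness
    mismatch, group-fairness mismatch), a minimal trainable
    message-passing classifier with gradient and random baseline
    explainers, dataset serialization, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
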