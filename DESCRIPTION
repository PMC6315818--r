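Package: unresqa
Title: Coarse-Grained Energy Decomposition and Neural-Network Scoring for
    Protein Model Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores protein decoy structures with a UNRES-style two-site
    coarse-grained effective energy whose repulsive pairwise contributions
    are capped so unminimized decoys remain scoreable.  The energy is
    decomposed into a 1296-entry residue-type-resolved feature vector and
    mapped to transformed TM-scores by an ensemble of small feed-forward
    neural networks trained by backpropagation with momentum and
    held-out-target overfit protection.  Includes a deterministic TM-score
    implementation (Kabsch superposition plus fragment-seeded iterative
    extension), a synthetic CASP-like decoy-set generator, and the decoy
    ranking statistics used to evaluate model quality assessment methods
    (top-5 mean TM-score, per-target Pearson correlation, directional
    accuracies, and path-to-native statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
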