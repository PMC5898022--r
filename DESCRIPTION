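Package: paretodr
Title: Drug Repositioning by Pareto-Dominance Collaborative Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts new disease indications for known drugs by treating
    repositioning as a recommendation problem. Drug-drug similarities are
    computed per data source (chemical substructures, protein targets,
    side-effect profiles) with cosine, Jaccard/Tanimoto or Smith-Waterman
    alignment measures; neighbour drugs are selected by iterated Pareto
    dominance over the per-feature similarity profiles; candidate diseases
    are scored from the neighbours' known indications by plain or
    similarity-weighted voting. Includes leave-one-out evaluation with
    precision/recall/F1 at k, specificity, AUC-PR and AUC-ROC, analytic
    upper-bound curves, and a planted-cluster synthetic data generator
    that emulates the sparsity structure of real drug-feature matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
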