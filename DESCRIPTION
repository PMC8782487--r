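Package: aaperturb
Title: Amino-Acid Perturbation Networks for Predicting Functionally
    Sensitive Protein Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted amino-acid networks from protein 3D
    coordinates (edge weights count inter-residue atom pairs closer
    than a distance threshold), computes perturbation networks as the
    pruned absolute difference between wild-type and mutant networks,
    and summarises each mutation by four topology measures (nodes,
    edges, weight, diameter). Standardized per-mutation scores feed a
    cutoff-vector classifier of structurally sensitive positions, which
    is evaluated against deep-mutational-scanning functional data with
    precision, recall, null scores, improvement factors, ROC/AUC,
    cutoff and threshold sweeps, and per-position Spearman
    correlations. Includes a synthetic structure/mutant/functional-data
    generator so the full pipeline runs without external mutagenesis
    software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
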