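Package: fr20
Title: Ferroptosis-Regulator Scoring of BET-Inhibitor Resistance and
    Connectivity-Based Re-Sensitizer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies BET bromodomain inhibitor (e.g. JQ1) resistance in
    triple-negative breast cancer transcriptomes with FR20, a signed sum of
    normalized expression over twenty dysregulated ferroptosis regulators
    (+1 for up-regulated suppressors, -1 for down-regulated drivers), and
    screens perturbation libraries for compounds predicted to reverse the
    resistance signature with D-FR20, a connectivity screen built on weighted
    Kolmogorov-Smirnov enrichment scores, permutation-normalized enrichment
    scores, and the weighted connectivity score (WTCS). Includes the full
    signature-derivation pipeline (quality control, library-size
    normalization, Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg correction, regulator-catalog intersection, Fisher
    enrichment checks), seeded negative-binomial and Gaussian synthetic-data
    generators so every stage is testable without external downloads, and a
    command-line interface covering the simulate/derive/score/screen
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    arrow,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
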