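Package: crossformat
Title: Cross-Format Analysis of Intended and Observed Actions in Neural
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for comparing neural population codes for
    intended and observed hand actions recorded with intracortical arrays.
    Implements single-unit responsiveness and latency statistics, time-resolved
    factorial ANOVA tuning, a ten-model cross-format linear-model taxonomy with
    permutation/FDR gating, split-half representational similarity analysis,
    within-format, cross-time and cross-format linear discriminant decoding,
    high-gamma local field potential extraction and decoding, and population
    geometry (PCA trajectories, Procrustes alignment, UMAP embeddings).
    Ships a synthetic-session generator that plants known coding structure
    (shared, single-format, mixed, idiosyncratic and relevance-gated units)
    so every stage is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
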