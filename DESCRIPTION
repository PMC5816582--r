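Package: hetarray
Title: Cross-Species Two-Color cDNA Microarray Analysis
Version: 0.1.0
Authors@R:
    person("hetarray", "maintainers", email = "hetarray@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for heterologous (cross-species) two-color
    cDNA microarray experiments: spot-level quality control with a
    signal-to-noise window and cross-species alignment filtering, two-stage
    ANOVA normalization (array/dye model followed by factor-wise log2
    ratios with loess intensity correction), per-gene linear models with
    Bonferroni family-wise error control, length-bias-aware category
    enrichment via the Wallenius noncentral hypergeometric distribution,
    topological-overlap coexpression module detection with module
    eigengenes, and a synthetic-data generator with known ground truth so
    every stage can be tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
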