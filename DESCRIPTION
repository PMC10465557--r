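Package: macrogd
Title: Macrogenetic Analysis of Barcode-Derived Mitochondrial Genetic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for class III macrogenetic analysis of georeferenced DNA
    barcode data. Reads BOLD-style specimen tables, applies record-level
    quality filters, assigns specimens to equal-area (Behrmann) grid cells,
    and computes per-OTU nucleotide diversity aggregated into per-cell
    genetic diversity mean (GDM) and Hill-number genetic diversity evenness
    (GDE). Provides spatially corrected correlation tests (Dutilleul's
    modified t-test, Moran's I permutation tests), a Bayesian spatial
    generalized linear mixed model with a knot-based random field for
    environmental regression and global prediction, multivariate
    environmental similarity (MESS) extrapolation masking, a Hudson
    coalescent simulator for generating synthetic barcode datasets with
    planted environment-diversity relationships, and an end-to-end pipeline
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
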