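Package: tadscape
Title: Integrative Analysis of 3D Genome Organization in Large Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying chromatin spatial organization
    in large, repeat-rich plant genomes from binned Hi-C contact matrices and
    companion genomic tracks. Provides matrix balancing by iterative
    correction, observed/expected and correlation transforms, PCA-based A/B
    compartment calls with a ranked hierarchical subcompartment stand-in,
    insulation-style TAD-like domain calling with three-class
    (active/inactive/heterochromatin-driven) classification, loop-set merging
    and cross-tissue sharing with boundary-association statistics,
    boundary-centered variant depletion profiles under a homogeneity null,
    synteny-break detection from alignment blocks with
    alignability-normalized permutation enrichment, binned methylation and
    coverage tracks, and tissue-specificity (tau) and fold-change analyses of
    binned expression. A synthetic-data module generates all inputs with
    planted ground truth so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
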