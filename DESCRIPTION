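Package: cellstab
Title: Linking Predicted Protein Stability Changes to Cellular Abundance,
    Degradation and Pathogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in silico saturation-mutagenesis stability
    predictions (ddG, kcal/mol) of missense variants and relating them to
    cellular phenotypes. Implements parsing and aggregation of
    replicate/chain-resolved ddG tables, a two-state thermodynamic model
    linking ddG to fraction folded, steady-state abundance and residual
    function with bootstrap estimation of the effective wild-type folding
    free energy, a pairwise maximum-entropy (Potts) model of multiple
    sequence alignments fit by regularised pseudolikelihood for
    covariation-based mutation-effect scoring, ROC and leave-one-out
    pathogenicity evaluation with bootstrap and permutation group tests,
    and seeded generators for synthetic datasets with the statistical
    structure the analysis assumes. Bundles a curated table of 24
    experimentally characterised MSH2 missense variants.
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
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
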