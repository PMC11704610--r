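Package: noisebench
Title: Quantifying Transcriptional Noise and Bursting from Single-Cell Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cell-to-cell transcriptional noise (CV^2 and
    Fano factor) from smFISH-style per-cell mRNA spot counts and scRNA-seq UMI
    count matrices, and to benchmark normalization methods against an smFISH
    reference. Includes a Gamma-Poisson (negative binomial) simulator of bursty
    gene expression with extrinsic cell-size coupling, binomial capture
    thinning and homeostatic treated/control pairs with known ground truth;
    quality-control and depth normalization for UMI matrices; an iterative
    cell-size extrinsic-noise filter with a permutation-test stopping rule;
    maximum-likelihood negative binomial inference of transcriptional burst
    size and burst frequency; and a combined deviation score for ranking
    normalization methods against smFISH fold changes.
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
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
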