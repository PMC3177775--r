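Package: mdrkit
Title: Multifactor Dimensionality Reduction for Detecting Gene-Gene
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric multifactor dimensionality reduction (MDR) for
    case-control genotype data.  Performs an exhaustive search over locus
    combinations, pooling multi-locus genotype cells into high-risk and
    low-risk classes and scoring each combination with balanced accuracy.
    Internal validation is provided through stratified k-fold
    cross-validation and three-way split (training/testing/validation)
    schemes, with summary, plot and predict methods for fitted models.
    Post-hoc inference includes permutation tests of prediction accuracy
    and a likelihood-ratio permutation test of interaction, plus
    prospective adjustment of retrospective accuracy estimates from a
    user-supplied disease prevalence (algebraic and bootstrap).  A
    penetrance-model simulator generates case-control datasets with noise
    loci in Hardy-Weinberg proportions and embedded multi-locus effects
    for method evaluation.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
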