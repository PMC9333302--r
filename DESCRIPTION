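Package: reproscore
Title: Reproducibility Scores for Biomarker-Set Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attaches a falsifiable reproducibility estimate to the set of
    biomarkers discovered from a two-class labeled data matrix. Implements
    the parameterized univariate discovery operator (per-feature pooled
    two-sample t-test with Benjamini-Hochberg or Bonferroni correction),
    the Jaccard-based reproducibility score, and resampling estimators
    that bound it from above (oRS, via doubling partitions; bRS, via
    class-stratified bootstrap pairs) and below (uRS, via disjoint
    halving), together with subset-size curves, a synthetic two-class
    generator with planted differential features for ground-truth
    Monte-Carlo validation, delimited-text readers and writers including
    SNP genotype encoding and survival dichotomization, and a
    command-line entry point producing seeded, regenerable reports.
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
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
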