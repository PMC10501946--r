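Package: mrfalsify
Title: Falsification Tests for Mendelian Randomization Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for falsifying the instrumental-variable conditions in
    Mendelian randomization studies with individual-level data. Implements
    Pearl's instrumental inequalities for single genetic variants, jointly
    cross-classified variant sets, and unweighted allele-score deciles,
    with optional stabilized inverse-probability weighting to adjust for
    population structure captured by principal components. Also provides
    reimplementations of two comparator falsification strategies, the
    MR-Egger intercept test and the MR-PRESSO global test, and a synthetic
    cohort generator that emulates biobank-style genotype, exposure and
    binary-outcome data with controllable pleiotropy, confounding,
    selection and population stratification.
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
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
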