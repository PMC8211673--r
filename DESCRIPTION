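Package: gutdrift
Title: Longitudinal Stability Analysis of Gut Microbiota Compositions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies year-to-year change in family-level gut microbiota
    compositions within a longitudinal cohort. Computes Jensen-Shannon
    distance (the square root of Jensen-Shannon divergence, with a
    pseudocount on the simplex) and Bray-Curtis dissimilarity between
    samples, decomposes them into intra-individual variation and
    inter-individual difference, classifies subjects whose composition
    changed substantially (JSD >= 0.4), types the persistence of change
    across three yearly waves, and tests associations between stability
    and a fermented-milk-intake covariate (Fisher's exact, chi-square,
    Steel's many-to-one rank test, covariate-adjusted group comparison,
    Levene's dispersion test, Spearman correlation, and PERMANOVA on
    distance matrices). Includes a calibrated logistic-normal cohort
    simulator so the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
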