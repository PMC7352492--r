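Package: nutrinet
Title: Systems-Nutrology Analysis of Food-Frequency Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 'systems nutrology' analysis of adolescent cohorts:
    conversion of semi-quantitative food-frequency questionnaire (FFQ)
    responses to daily food-group intakes in grams, classification of
    anthropometric status from BMI-for-age percentiles and of divergence
    between measured and perceived weight (DMPW), ecology-style abundance
    of consumption transformation with Ward hierarchical dietary-pattern
    clustering, multinomial dietary-pattern regression with design-effect
    diagnostics, and bootstrap-stabilized signed Spearman correlation
    networks of food-group co-consumption with density and node-degree
    statistics. A synthetic-cohort generator with planted ground truth
    supports end-to-end parameter-recovery testing.
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
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
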