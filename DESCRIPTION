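Package: hyporules
Title: Association-Rule Classification of Tumor Hypoxia from a Three-Marker
    Immunohistochemistry Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies neuroblastoma tumors as hypoxic or normoxic from
    semiquantitative immunohistochemistry scores of three hypoxia markers
    (HIF-1alpha, PDK1, PHD3). Percentage-positivity bins are dichotomized to
    binary high/low marker states (medium cases resolved by staining
    intensity), association rules linking marker states to hypoxic status are
    mined with a from-scratch APRIORI implementation, and each rule is scored
    with five interestingness metrics (coverage as consequent recall,
    confidence, lift, leverage, and a smoothed conviction). Includes a
    packaged 25-tumor cohort, an exhaustive consistency audit of the
    medium-cell resolutions, a synthetic-cohort generator with known
    sensitivity/specificity structure for parameter-recovery experiments, and
    a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
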