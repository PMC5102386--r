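Package: trithresh
Title: Trichotomization of Diagnostic Test Scores with the Uncertain Interval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-way (negative / inconclusive / positive)
    interpretation of diagnostic test scores. Locates the intersection of the
    score distributions of subjects with and without a target condition and
    searches for an Uncertain Interval around it in which within-interval
    sensitivity and specificity stay below a pre-selected bound, so that
    correct and false calls are nearly balanced and no decision is warranted.
    Includes the nonparametric Two-Graph ROC (TG-ROC) comparator, seven
    classical single-threshold criteria (maximized Youden index and others),
    trichotomous decision-table quality reports, mixed probability histograms
    and density plots, and a binormal Monte-Carlo simulation framework for
    comparing the methods across test strengths and prevalences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
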