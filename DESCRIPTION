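Package: quadconc
Title: Model-Based Concordance Rates for Four-Quadrant Plots of Repeated
    Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trending-agreement analysis for method-comparison studies with
    repeated measurements. Implements the conventional concordance rate of the
    four-quadrant plot with an exclusion zone, two binomial control estimators
    for "at least m of T" agreement, and a model-based concordance rate defined
    as a conditional probability under a multivariate normal model fitted to
    the within-subject difference vectors, evaluated exactly by signed-rectangle
    inclusion-exclusion over multivariate normal rectangle probabilities.
    Includes a Monte Carlo cross-check of the analytic rate, a full factorial
    simulation study of estimator diagnosability with ROC/AUC and Youden-index
    evaluation, a bootstrap protocol for triple-method blood-pressure data, and
    a synthetic generator for such data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
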