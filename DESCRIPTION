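Package: waitcea
Title: Trial-Based Cost-Effectiveness and Value-of-Information Analysis for Waitlist RCTs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Economic evaluation alongside a two-arm waitlist randomized
    controlled trial: per-outcome treatment effects at 3, 6 and 9 months
    after exposure with counterfactual chaining beyond the controlled
    horizon, discounted area-under-the-curve aggregation into QALYs and
    costs, resource-use costing with mixed recall windows, analytic
    cost-effectiveness acceptability curves on the bivariate-normal
    cost-effectiveness plane, expected value of (partial) perfect
    information via the unit normal loss integral, and a sensitivity
    analysis grid (difference-in-differences, baseline adjustment,
    pre-post, attrition scenarios, multiple imputation by predictive
    mean matching, costing scope). Includes a calibrated synthetic trial
    generator so the whole pipeline is testable without microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    sandwich,
    withr,
    knitr
Config/testthat/edition: 3
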