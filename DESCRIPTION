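Package: steppedcea
Title: Cost-Utility Modelling of Collaborative Stepped Care for Depression
    and Anxiety in Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A quasi-decision-tree cost-utility model comparing a
    collaborative stepped care (CSC) intervention against care-as-usual
    (CAU) for adult depression and/or anxiety in a primary-care setting.
    Computes disability-adjusted life years averted by area-under-the-curve
    person-time over three 4-month remission intervals, costs intervention
    pathways with treatment cost offsets, and reports incremental
    cost-effectiveness ratios with dominance classification. Includes
    probabilistic sensitivity analysis (Monte Carlo over beta/gamma/
    lognormal parameter uncertainty, cost-effectiveness planes and
    acceptability curves), univariate tornado analysis, scenario analyses,
    a declarative JSON parameter schema and a synthetic parameter
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
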