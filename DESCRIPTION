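Package: medafford
Title: Cross-Country Price Indices and Catastrophic Expenditure Analysis
    for Branded Medicines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing retail prices of branded pharmaceuticals
    across countries from a single reference-country perspective. Builds a
    sales-value-weighted bilateral Laspeyres price index, adjusts it by GDP
    purchasing-power-parity per capita to express affordability, normalizes
    pack prices to defined-daily-dose (DDD) and standardized monthly
    treatment costs, and classifies per-treatment catastrophic pharmaceutical
    expenditure against minimum-wage thresholds, with population-share
    estimation under parametric or empirical income distributions. Includes a
    seeded synthetic-data generator emulating the statistical structure of
    country price panels, heavy-tailed sales weights and lognormal incomes,
    and a small worked-example fixture of monthly treatment costs for eight
    chronic conditions in five euro-area countries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
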